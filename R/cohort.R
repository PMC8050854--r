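#' Construct a patient cohort
#'
#' A cohort maps each patient to its set of altered genes, with optional
#' reference subgroup labels (e.g. the WNT/SHH/G3/G4 medulloblastoma
#' subgroups). Labels may cover only part of the cohort; unlabeled patients
#' are treated as held-out.
#'
#' @param patients Named list of character vectors (patient id -> altered
#'   genes), or a long data frame with columns `patient` and `gene`.
#' @param labels Optional named character vector (patient id -> subgroup), or
#'   a data frame with columns `patient` and `subgroup`.
#' @return An object of class `cohort`: list with `patients` (named list of
#'   sorted unique gene vectors) and `labels` (named character vector).
#' @export
cohort <- function(patients, labels = NULL) {
  if (is.data.frame(patients)) {
    stopifnot(all(c("patient", "gene") %in% names(patients)))
    patients <- split(as.character(patients$gene), as.character(patients$patient))
  }
  if (is.null(names(patients)) || anyDuplicated(names(patients))) {
    stop("patient ids must be unique and named", call. = FALSE)
  }
  patients <- lapply(patients, function(g) sort(unique(as.character(g))))
  empty <- names(patients)[lengths(patients) == 0]
  if (length(empty)) {
    stop("empty gene set for patient(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  lab <- character(0)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      stopifnot(all(c("patient", "subgroup") %in% names(labels)))
      lab <- stats::setNames(as.character(labels$subgroup), as.character(labels$patient))
    } else {
      lab <- stats::setNames(as.character(labels), names(labels))
    }
    unknown <- setdiff(names(lab), names(patients))
    if (length(unknown)) {
      stop("label(s) for unknown patient(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(patients = patients, labels = lab), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("A cohort: ", length(x$patients), " patients (",
      length(x$labels), " labeled), ",
      length(unique(unlist(x$patients))), " distinct genes\n", sep = "")
  invisible(x)
}

#' @method as_tibble cohort
#' @export
as_tibble.cohort <- function(x, ...) {
  tibble::tibble(
    patient = rep(names(x$patients), lengths(x$patients)),
    gene = unlist(x$patients, use.names = FALSE)
  )
}

#' Patient ids of a cohort
#' @param x A `cohort`.
#' @return Character vector.
#' @export
patient_ids <- function(x) {
  stopifnot(inherits(x, "cohort"))
  names(x$patients)
}

#' Read a cohort from disk
#'
#' The gene file is either a long TSV with columns `patient`, `gene` (header
#' optional) or a JSON object mapping patient ids to gene arrays. Labels, if
#' given, are a comma- or tab-separated file with columns `patient`,
#' `subgroup`.
#'
#' @param genes_path Path to the per-patient altered-gene file.
#' @param labels_path Optional path to the reference-subgroup file.
#' @return A [cohort()] object.
#' @export
load_cohort <- function(genes_path, labels_path = NULL) {
  if (!file.exists(genes_path)) stop("file not found: ", genes_path, call. = FALSE)
  if (grepl("\\.json$", genes_path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(genes_path, simplifyVector = TRUE)
    patients <- lapply(lst, as.character)
  } else {
    raw <- readr::read_tsv(
      genes_path, col_names = FALSE,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    if (ncol(raw) < 2) stop("gene file needs columns patient, gene", call. = FALSE)
    if (identical(tolower(raw[[1]][1]), "patient")) raw <- raw[-1, , drop = FALSE]
    patients <- split(raw[[2]], raw[[1]])
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(
      labels_path, sep = if (grepl("\\.csv$", labels_path)) "," else "\t",
      header = TRUE, stringsAsFactors = FALSE
    )
    names(lab)[1:2] <- c("patient", "subgroup")
    labels <- lab[, 1:2]
  }
  cohort(patients, labels)
}

#' Write a cohort (and labels) to disk
#' @param x A `cohort`.
#' @param genes_path Output TSV path (long, `patient`/`gene`, with header).
#' @param labels_path Optional output CSV path (`patient`,`subgroup`).
#' @return `genes_path`, invisibly.
#' @export
write_cohort <- function(x, genes_path, labels_path = NULL) {
  stopifnot(inherits(x, "cohort"))
  readr::write_tsv(as_tibble.cohort(x), genes_path)
  if (!is.null(labels_path) && length(x$labels)) {
    utils::write.csv(
      data.frame(patient = names(x$labels), subgroup = unname(x$labels)),
      labels_path, row.names = FALSE, quote = FALSE
    )
  }
  invisible(genes_path)
}

#' Restrict a cohort to the genes of a network
#'
#' Intersects each patient's altered-gene set with the network node universe
#' (genes absent from the network carry no trajectory and cannot inform the
#' downstream selection). Dropped counts are reported via a message and kept
#' in the `dropped` attribute.
#'
#' @param x A `cohort`.
#' @param net A `multiplex` network, or a character vector of node ids.
#' @return The restricted `cohort`, with attribute `dropped` (named integer).
#' @export
restrict_to_network <- function(x, net) {
  stopifnot(inherits(x, "cohort"))
  universe <- if (inherits(net, "multiplex")) net$nodes else as.character(net)
  kept <- lapply(x$patients, intersect, y = universe)
  empty <- names(kept)[lengths(kept) == 0]
  if (length(empty)) {
    stop("no genes left in the network for patient(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  dropped <- lengths(x$patients) - lengths(kept)
  if (sum(dropped) > 0) {
    message(sum(lengths(kept)), " of ", sum(lengths(x$patients)),
            " patient-gene records retained (", sum(dropped), " dropped)")
  }
  out <- cohort(kept, if (length(x$labels)) x$labels else NULL)
  attr(out, "dropped") <- dropped
  out
}
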