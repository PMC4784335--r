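# Expression data model, file I/O and preprocessing.

#' Construct a study bundle
#'
#' A study bundle holds one exposure-duration dataset: a probes x samples
#' log2 expression matrix, the sample annotation table, the measured tissue
#' residue vector and (for synthetic data) the generator's ground truth.
#' Sample ids must match across components; the annotation order is canonical.
#'
#' @param expression numeric matrix, probes in rows, samples in columns.
#' @param annotation data.frame with at least `sample_id` and `class_label`.
#' @param residue named numeric vector of measured residues (>= 0).
#' @param truth optional `synthetic_truth` record.
#' @return an object of class `study_bundle`.
#' @export
study_bundle <- function(expression, annotation, residue, truth = NULL) {
  if (is.null(colnames(expression))) stop("expression needs sample column names")
  if (!identical(colnames(expression), annotation$sample_id) ||
      !identical(names(residue), annotation$sample_id)) {
    stop("integrity error: sample ids differ or are ordered differently ",
         "across components; use align_bundle()")
  }
  if (any(residue < 0, na.rm = TRUE)) stop("residue values must be >= 0")
  if (anyDuplicated(rownames(expression))) stop("duplicate probe ids")
  structure(list(expression = expression, annotation = annotation,
                 residue = residue, truth = truth),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("study_bundle: %d probes x %d samples (%s, %g d)\n",
              nrow(x$expression), ncol(x$expression),
              x$annotation$compound[1], x$annotation$duration[1]))
  invisible(x)
}

.scale_tag <- function(x) attr(x, "scale_tag") %||% "log2"

#' Read an expression matrix from a tab-delimited file
#'
#' `plain_tsv`: header row of sample ids after a probe-id column, one row per
#' probe. `series_matrix_like` additionally tolerates `!`-prefixed metadata
#' lines and quoted fields (the table section of a GEO series matrix, whose
#' probe column is usually named `ID_REF`).
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"series_matrix_like"`.
#' @return numeric matrix with probe rownames and sample colnames; non-numeric
#'   cells become NA (flagged missing). Attribute `scale_tag` is `"log2"`
#'   unless the file carries raw intensities (callers may reset it).
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("plain_tsv",
                                               "series_matrix_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "series_matrix_like") {
    lines <- lines[!startsWith(lines, "!")]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) {
    stop("format error: ragged rows (rows have differing field counts)")
  }
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  probes <- vapply(body, `[[`, character(1), 1)
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    stop("format error: duplicated probe id: ", paste(unique(dup), collapse = ", "))
  }
  vals <- if (length(body)) {
    t(vapply(body, function(f) {
      suppressWarnings(as.numeric(f[-1]))
    }, numeric(length(samples))))
  } else matrix(numeric(0), 0, length(samples))
  if (length(samples) == 1 && length(body)) vals <- matrix(vals, ncol = 1)
  dimnames(vals) <- list(probes, samples)
  attr(vals, "scale_tag") <- "log2"
  vals
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()] for the `plain_tsv` dialect; values
#' are printed with 17 significant digits so the round trip is numerically
#' exact.
#'
#' @param x probes x samples matrix.
#' @param path output path.
#' @param dialect output dialect (plain TSV only).
#' @param id_column name of the probe-id column in the header.
#' @export
write_expression_matrix <- function(x, path, dialect = "plain_tsv",
                                    id_column = "probe_id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  if (nrow(x)) {
    body <- apply(x, 2, function(col) {
      out <- formatC(col, digits = 17, format = "g")
      out[is.na(col)] <- "NA"
      out
    })
    body <- matrix(body, nrow = nrow(x))
    writeLines(paste(rownames(x),
                     apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Align expression, annotation and residue into a study bundle
#'
#' Components are restricted to the sample-id intersection and reordered to
#' the annotation order (the canonical ordering); dropped samples are
#' reported with a message and recorded in attribute `dropped`.
#'
#' @param expression probes x samples matrix.
#' @param annotation annotation data.frame.
#' @param residue named residue vector.
#' @param truth optional truth record.
#' @return a `study_bundle`.
#' @export
align_bundle <- function(expression, annotation, residue, truth = NULL) {
  common <- intersect(intersect(annotation$sample_id, colnames(expression)),
                      names(residue))
  if (!length(common)) {
    stop("integrity error: no sample ids shared by all components")
  }
  keep <- annotation$sample_id[annotation$sample_id %in% common]
  dropped <- unique(c(setdiff(annotation$sample_id, keep),
                      setdiff(colnames(expression), keep),
                      setdiff(names(residue), keep)))
  if (length(dropped)) {
    message("align_bundle: dropped ", length(dropped), " sample(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  tag <- .scale_tag(expression)
  expression <- expression[, keep, drop = FALSE]
  attr(expression, "scale_tag") <- tag
  b <- study_bundle(expression,
                    annotation[match(keep, annotation$sample_id), , drop = FALSE],
                    residue[keep], truth = truth)
  attr(b, "dropped") <- dropped
  b
}

#' Preprocess an expression matrix
#'
#' Applies the requested steps in order. Available steps:
#' \describe{
#'   \item{filter_missing}{drop probes whose missing fraction exceeds
#'     `missing_threshold`.}
#'   \item{log2}{log2-transform raw intensities (after adding `log_offset`);
#'     refuses non-positive values unless the offset fixes them, and refuses
#'     to transform a matrix already on log2 scale.}
#'   \item{quantile_normalize}{quantile normalization across samples
#'     (limma; ties share the average of their reference quantiles).}
#'   \item{median_center}{subtract each sample's median.}
#' }
#' The default recipe for raw data is
#' `c("filter_missing", "log2", "quantile_normalize")`.
#'
#' @param x expression matrix with a `scale_tag` attribute
#'   ("raw", "log2" or "normalized").
#' @param steps character vector of step names, applied left to right.
#' @param missing_threshold maximum tolerated per-probe missing fraction.
#' @param log_offset constant added before the log2 step.
#' @return the processed matrix with an updated `scale_tag`.
#' @export
preprocess <- function(x,
                       steps = c("filter_missing", "log2",
                                 "quantile_normalize"),
                       missing_threshold = 0.5,
                       log_offset = 0) {
  tag <- .scale_tag(x)
  for (step in steps) {
    x <- switch(step,
      filter_missing = {
        frac <- rowMeans(is.na(x))
        x[frac <= missing_threshold, , drop = FALSE]
      },
      log2 = {
        if (tag != "raw") {
          stop("domain error: log2 requested but matrix is already on '",
               tag, "' scale")
        }
        v <- x + log_offset
        if (any(v <= 0, na.rm = TRUE)) {
          stop("domain error: log2 of non-positive values; ",
               "configure log_offset")
        }
        tag <- "log2"
        log2(v)
      },
      quantile_normalize = {
        tag <- "normalized"
        out <- limma::normalizeQuantiles(x, ties = TRUE)
        as.matrix(out)
      },
      median_center = {
        sweep(x, 2, apply(x, 2, stats::median, na.rm = TRUE))
      },
      stop("unknown preprocessing step: ", step))
  }
  attr(x, "scale_tag") <- tag
  x
}

#' Mean-impute remaining missing values per probe
#'
#' Probes that are entirely missing are imputed with the overall mean.
#'
#' @param x expression matrix.
#' @return matrix without NA values.
#' @export
impute_missing <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- rowMeans(x, na.rm = TRUE)
  mu[!is.finite(mu)] <- mean(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 1]]
  x
}

#' Write a study bundle as plain-text files
#'
#' Writes `expression.tsv`, `annotation.tsv`, `residue.tsv` and, when a truth
#' record is present, `truth.txt` (a key/tab-separated-value format; vector
#' values are comma-joined).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  utils::write.table(bundle$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(bundle$residue),
               residue = formatC(bundle$residue, digits = 17, format = "g")),
    file.path(dir, "residue.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    lines <- c(
      paste0("residue_linked_ids\t", paste(tr$residue_linked_ids, collapse = ",")),
      paste0("residue_linked_beta\t",
             paste(formatC(tr$residue_linked_beta, digits = 17, format = "g"),
                   collapse = ",")),
      paste0("dose_responsive_ids\t", paste(tr$dose_responsive_ids, collapse = ",")),
      paste0("batch_affected_ids\t", paste(tr$batch_affected_ids, collapse = ",")),
      paste0("seed\t", tr$seed))
    writeLines(lines, file.path(dir, "truth.txt"))
  }
  invisible(dir)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a `study_bundle` (truth, if present, as a plain list).
#' @export
read_study_bundle <- function(dir) {
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  ann <- utils::read.delim(file.path(dir, "annotation.tsv"),
                           stringsAsFactors = FALSE)
  res <- utils::read.delim(file.path(dir, "residue.tsv"),
                           stringsAsFactors = FALSE)
  residue <- stats::setNames(as.numeric(res$residue), res$sample_id)
  truth <- NULL
  tf <- file.path(dir, "truth.txt")
  if (file.exists(tf)) {
    kv <- strsplit(readLines(tf), "\t", fixed = TRUE)
    truth <- stats::setNames(
      lapply(kv, function(x) if (length(x) > 1) strsplit(x[2], ",")[[1]] else
        character(0)),
      vapply(kv, `[[`, character(1), 1))
  }
  align_bundle(expr, ann, residue, truth = truth)
}

#' Read a study configuration (YAML)
#'
#' The file mirrors the constructor arguments under top-level keys `design`,
#' `uptake` and `signal`; omitted fields take the package defaults.
#'
#' @param path YAML file path.
#' @return list with elements `design`, `uptake`, `signal`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(exposure_design, cfg$design %||% list())
  uptake <- do.call(uptake_params, cfg$uptake %||% list())
  signal <- do.call(signal_config, cfg$signal %||% list())
  list(design = design, uptake = uptake, signal = signal)
}
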