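# Predictor gene set construction: DE-list set algebra, correlation ranking
# against tissue residue, extreme-gene augmentation and the incremental scan.

#' Construct a predictor set
#'
#' @param probe_ids character vector of probe ids.
#' @param tag provenance tag per probe: "DE", "top_corr" or "bottom_corr".
#' @param source free-text source label(s) (e.g. which comparison).
#' @return an object of class `predictor_set` (a data.frame with columns
#'   probe_id, tag, source); duplicated ids collapse, the "DE" tag winning.
#' @export
predictor_set <- function(probe_ids, tag = "DE", source = "") {
  df <- data.frame(probe_id = as.character(probe_ids),
                   tag = rep_len(as.character(tag), length(probe_ids)),
                   source = rep_len(as.character(source), length(probe_ids)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$tag != "DE"), , drop = FALSE]  # DE first, then extremes
  df <- df[!duplicated(df$probe_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("predictor_set", "data.frame")
  df
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("predictor_set: %d genes (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$tag)), table(x$tag)),
                    collapse = ", ")))
  invisible(x)
}

#' Intersect two DE lists and exclude control-difference genes
#'
#' Returns `(de_original ∩ de_repeat) \ de_controls` — the genes responding
#' in both exposures minus those also separating the two control groups
#' (i.e. batch-driven genes). Stage counts are kept in attribute
#' `stage_counts`.
#'
#' @param de_original,de_repeat,de_controls `de_gene_set` objects over the
#'   same probe universe.
#' @return a `predictor_set` tagged "DE".
#' @export
intersect_exclude <- function(de_original, de_repeat, de_controls) {
  universes <- lapply(list(de_original, de_repeat, de_controls),
                      function(d) sort(names(d$p_value)))
  if (!identical(universes[[1]], universes[[2]]) ||
      !identical(universes[[1]], universes[[3]])) {
    stop("integrity error: DE sets cover different probe universes")
  }
  common <- intersect(de_original$probe_ids, de_repeat$probe_ids)
  final <- setdiff(common, de_controls$probe_ids)
  out <- predictor_set(final, tag = "DE",
                       source = paste(de_original$comparison_label,
                                      de_repeat$comparison_label, sep = "+"))
  attr(out, "stage_counts") <- c(
    original = length(de_original$probe_ids),
    repeated = length(de_repeat$probe_ids),
    common = length(common),
    excluded = length(common) - length(final),
    final = length(final))
  out
}

#' Rank probes by Pearson correlation with tissue residue
#'
#' @param x probes x samples matrix.
#' @param residue residue vector aligned with the columns of `x`.
#' @return an object of class `correlation_ranking`: data.frame
#'   (probe_id, r, rank, flagged) ordered by descending r; rank 1 is the most
#'   positively correlated probe. Zero-variance probes get r = 0 and
#'   `flagged = TRUE`. Ties in r break lexicographically by probe id.
#' @export
correlation_rank <- function(x, residue) {
  if (ncol(x) < 3) stop("need >= 3 samples")
  if (length(residue) != ncol(x)) stop("residue length must match samples")
  if (stats::sd(residue) == 0) {
    stop("degenerate-input error: residue is constant")
  }
  r <- suppressWarnings(as.numeric(stats::cor(t(x), residue)))
  flagged <- !is.finite(r)
  r[flagged] <- 0
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  ord <- order(-r, ids)
  out <- data.frame(probe_id = ids[ord], r = r[ord],
                    rank = seq_along(ord), flagged = flagged[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' Probes passing an absolute-correlation cutoff
#'
#' @param ranking a `correlation_ranking`.
#' @param cutoff |r| threshold in (0, 1].
#' @return the ranking rows with |r| >= cutoff, preserving rank order.
#' @export
threshold_correlated <- function(ranking, cutoff = 0.6) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  out <- ranking[abs(ranking$r) >= cutoff, , drop = FALSE]
  attr(out, "cutoff_used") <- cutoff
  out
}

#' Augment a DE predictor set with correlation extremes
#'
#' Adds the `n_top` most positively and `n_bottom` most negatively
#' residue-correlated probes to a DE set. When `cutoff` is given the
#' extremes are drawn from the |r|-thresholded list (the default behavior of
#' the selection workflow); duplicates collapse with the "DE" tag winning.
#'
#' @param de_set a `predictor_set` (may be empty).
#' @param ranking a `correlation_ranking`.
#' @param n_top,n_bottom number of extreme genes from each end.
#' @param cutoff optional |r| cutoff restricting the candidate list.
#' @return a `predictor_set`; attribute `n_overlap` counts extremes that were
#'   already in the DE set.
#' @export
augment_with_extremes <- function(de_set, ranking, n_top = 2, n_bottom = 2,
                                  cutoff = NULL) {
  pool <- if (is.null(cutoff)) ranking else threshold_correlated(ranking, cutoff)
  # "top" genes must be positively, "bottom" genes negatively correlated;
  # a small pool yields fewer extremes rather than sign-crossing picks
  top <- utils::head(pool$probe_id[pool$r > 0], n_top)
  bottom <- utils::tail(pool$probe_id[pool$r < 0], n_bottom)
  bottom <- setdiff(bottom, top)
  extremes <- data.frame(
    probe_id = c(top, bottom),
    tag = c(rep("top_corr", length(top)), rep("bottom_corr", length(bottom))),
    source = rep("correlation", length(top) + length(bottom)),
    stringsAsFactors = FALSE)
  overlap <- sum(extremes$probe_id %in% de_set$probe_id)
  combined <- rbind(as.data.frame(de_set)[, c("probe_id", "tag", "source")],
                    extremes)
  out <- predictor_set(combined$probe_id, combined$tag, combined$source)
  attr(out, "n_overlap") <- overlap
  out
}

#' Incremental extreme-gene augmentation scan
#'
#' Evaluates predictor sets `DE ∪ (top j, bottom k)` for j, k over multiples
#' of the step sizes (plus 0) up to `cap`, scoring each with a user-supplied
#' cross-validated evaluator, and returns the full grid together with the
#' best-scoring set. With an empty ranking only the bare DE set is scored.
#'
#' @param de_set a `predictor_set`.
#' @param ranking a `correlation_ranking` (may have zero rows).
#' @param evaluator `function(probe_ids) -> mean R2` (NA/error allowed).
#' @param step_sizes increments to scan (default c(2, 3)).
#' @param cap largest j or k scanned.
#' @param cutoff optional |r| cutoff for the candidate list.
#' @return list with `grid` (data.frame j, k, n_genes, r2), `best_j`,
#'   `best_k`, `chosen` (a `predictor_set` or NULL) and `status`
#'   ("ok", "empty_ranking" or "no_valid_cell"). Ties prefer the smallest
#'   j + k, then the smallest j.
#' @export
incremental_scan <- function(de_set, ranking, evaluator,
                             step_sizes = c(2, 3), cap = 10,
                             cutoff = NULL) {
  steps <- sort(unique(c(0, unlist(lapply(step_sizes[step_sizes <= cap],
                                          function(s) seq(s, cap, by = s))))))
  if (nrow(ranking) == 0) {
    r2 <- tryCatch(evaluator(de_set$probe_id), error = function(e) NA_real_)
    return(list(grid = data.frame(j = 0, k = 0, n_genes = nrow(de_set),
                                  r2 = r2),
                best_j = 0, best_k = 0, chosen = de_set,
                status = "empty_ranking"))
  }
  grid <- expand.grid(j = steps, k = steps)
  grid$n_genes <- NA_integer_
  grid$r2 <- NA_real_
  sets <- vector("list", nrow(grid))
  cache <- new.env(parent = emptyenv())  # cells often induce identical sets
  for (i in seq_len(nrow(grid))) {
    set_i <- augment_with_extremes(de_set, ranking, grid$j[i], grid$k[i],
                                   cutoff = cutoff)
    sets[[i]] <- set_i
    grid$n_genes[i] <- nrow(set_i)
    if (nrow(set_i) == 0) next
    key <- paste(sort(set_i$probe_id), collapse = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(evaluator(set_i$probe_id),
                               error = function(e) NA_real_)
    }
    grid$r2[i] <- cache[[key]]
  }
  if (all(is.na(grid$r2))) {
    return(list(grid = grid, best_j = NA, best_k = NA, chosen = NULL,
                status = "no_valid_cell"))
  }
  ord <- order(-grid$r2, grid$j + grid$k, grid$j, na.last = TRUE)
  best <- ord[1]
  list(grid = grid, best_j = grid$j[best], best_k = grid$k[best],
       chosen = sets[[best]], status = "ok")
}

#' Serialize a predictor set as TSV
#'
#' @param set a `predictor_set`.
#' @param path output path.
#' @param ranking optional `correlation_ranking` to annotate each gene's r.
#' @export
write_predictor_set <- function(set, path, ranking = NULL) {
  out <- as.data.frame(set)
  if (!is.null(ranking)) {
    out$r <- ranking$r[match(out$probe_id, ranking$probe_id)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
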