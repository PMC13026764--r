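#' Read a virtual-screening score table
#'
#' CSV with columns `ligand_id`, `label` (`active`/`decoy`) and one or more
#' per-structure score columns (docking scores; lower = better). Use
#' `higher_is_better = TRUE` to negate scores whose convention is reversed.
#'
#' @param path CSV file
#' @param higher_is_better negate scores at ingestion (default `FALSE`)
#' @return a `screening_table` data.frame with `ligand_id`, `label` and
#'   score columns
#' @export
read_screening_table <- function(path, higher_is_better = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "label") %in% names(tab))) {
    stop("screening table needs 'ligand_id' and 'label' columns")
  }
  score_cols <- setdiff(names(tab), c("ligand_id", "label"))
  if (length(score_cols) == 0) stop("screening table has no score columns")
  if (anyDuplicated(tab$ligand_id)) stop("ligand_id values must be unique")
  bad <- setdiff(unique(tab$label), c("active", "decoy"))
  if (length(bad) > 0) stop("labels must be 'active'/'decoy'; found: ",
                            paste(bad, collapse = ", "))
  if (higher_is_better) tab[score_cols] <- -tab[score_cols]
  class(tab) <- c("screening_table", "data.frame")
  attr(tab, "score_cols") <- score_cols
  tab
}

#' Aggregate per-structure docking scores into one score per ligand
#'
#' With `method = "best"` (the ensemble-docking convention) each ligand
#' keeps its most favorable -- i.e. minimum -- score over the docked
#' structures; `mean` and `median` are available as alternatives. Missing
#' per-structure scores are ignored; a ligand with no finite score is
#' excluded with a warning.
#'
#' @param table a `screening_table` (or data.frame shaped like one)
#' @param method `"best"`, `"mean"` or `"median"`
#' @return data.frame with `ligand_id`, `label`, `score`
#' @export
aggregate_scores <- function(table, method = c("best", "mean", "median")) {
  method <- match.arg(method)
  score_cols <- attr(table, "score_cols")
  if (is.null(score_cols)) {
    score_cols <- setdiff(names(table), c("ligand_id", "label"))
  }
  scores <- as.matrix(table[score_cols])
  agg <- apply(scores, 1, function(s) {
    s <- s[is.finite(s)]
    if (length(s) == 0) return(NA_real_)
    switch(method, best = min(s), mean = mean(s), median = stats::median(s))
  })
  drop <- is.na(agg)
  if (any(drop)) {
    warning("excluding ", sum(drop), " ligand(s) with no finite score: ",
            paste(utils::head(table$ligand_id[drop], 5), collapse = ", "))
  }
  data.frame(ligand_id = table$ligand_id[!drop],
             label = table$label[!drop],
             score = agg[!drop],
             stringsAsFactors = FALSE)
}

#' Receiver operating characteristic curve
#'
#' Sweeps a threshold over the unique scores (lower score = predicted
#' active, the docking convention); tied scores enter the curve as a single
#' vertex. The curve runs from (0, 0) to (1, 1) with both coordinates
#' non-decreasing.
#'
#' @param labels character vector of `active`/`decoy` (or logical, `TRUE` =
#'   active)
#' @param scores numeric scores, lower = better
#' @return a `roc_curve`: data.frame with columns `fpr`, `tpr` and
#'   attributes `n_active`, `n_decoy`
#' @export
roc_curve <- function(labels, scores) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "active"
  }
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  n_act <- sum(labels)
  n_dec <- sum(!labels)
  if (n_act == 0 || n_dec == 0) {
    stop("both classes must be present (", n_act, " actives, ", n_dec,
         " decoys)")
  }
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  # group ties: one vertex after each distinct score value
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  cum_tp <- cumsum(l)[grp_end]
  cum_fp <- cumsum(!l)[grp_end]
  out <- data.frame(fpr = c(0, cum_fp / n_dec), tpr = c(0, cum_tp / n_act))
  attr(out, "n_active") <- n_act
  attr(out, "n_decoy") <- n_dec
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal area; with the tie-grouped curve of [roc_curve()] this
#' equals the midrank (Mann-Whitney) statistic divided by
#' `n_active * n_decoy`.
#'
#' @param curve a `roc_curve`
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Enrichment factor at a fixed false-positive rate
#'
#' `ER = TPR(fpr_level) / fpr_level`, with the TPR linearly interpolated on
#' the ROC curve at the requested FPR (the discrete curve rarely has a
#' vertex exactly there). The default level 0.01 gives the early-recognition
#' metric "enrichment at 1% FPR": how many times more actives than chance
#' are recovered while accepting 1% of decoys.
#'
#' @param curve a `roc_curve`
#' @param fpr_level false-positive rate in (0, 1]; default 0.01
#' @return enrichment factor (>= 0; 1 means no enrichment)
#' @export
enrichment_at_fpr <- function(curve, fpr_level = 0.01) {
  stopifnot(inherits(curve, "roc_curve"), fpr_level > 0, fpr_level <= 1)
  tpr <- stats::approx(curve$fpr, curve$tpr, xout = fpr_level,
                       ties = "ordered", rule = 2)$y
  tpr / fpr_level
}

#' Actives among the top-ranked ligands
#'
#' Number of actives among the `n` best (lowest) scores. Ties at the
#' boundary are broken deterministically by `ligand_id` order (or input
#' order when no ids are given). With fewer than `n` ligands the count runs
#' over all of them, with a warning.
#'
#' @param labels `active`/`decoy` labels (or logical)
#' @param scores numeric scores, lower = better
#' @param n ranking depth (default 50)
#' @param ligand_id optional ids used for deterministic tie-breaking
#' @return integer count of actives in the top `n`
#' @export
top_n_hits <- function(labels, scores, n = 50, ligand_id = NULL) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "active"
  }
  stopifnot(n >= 1, length(labels) == length(scores))
  if (is.null(ligand_id)) ligand_id <- seq_along(scores)
  if (length(scores) < n) {
    warning("only ", length(scores), " ligands for top-", n, " count")
    n <- length(scores)
  }
  ord <- order(scores, ligand_id)
  sum(labels[ord[seq_len(n)]])
}

#' Full screening evaluation of an ensemble-docking score table
#'
#' Aggregates per-structure scores ([aggregate_scores()]), then reports the
#' ROC AUC, the enrichment factor at the requested FPR and the number of
#' actives in the top `n`.
#'
#' @param table a `screening_table`
#' @param method aggregation method (see [aggregate_scores()])
#' @param top_n ranking depth (default 50)
#' @param fpr_level FPR for the enrichment factor (default 0.01)
#' @return a `screen_metrics` list: `auc`, `er`, `top_hits`, `n_active`,
#'   `n_decoy`, the parameters used, and the `roc` curve
#' @export
screen_metrics <- function(table, method = "best", top_n = 50,
                           fpr_level = 0.01) {
  agg <- aggregate_scores(table, method = method)
  curve <- roc_curve(agg$label, agg$score)
  structure(list(
    auc = roc_auc(curve),
    er = enrichment_at_fpr(curve, fpr_level),
    top_hits = top_n_hits(agg$label, agg$score, n = top_n,
                          ligand_id = agg$ligand_id),
    n_active = attr(curve, "n_active"),
    n_decoy = attr(curve, "n_decoy"),
    method = method, top_n = top_n, fpr_level = fpr_level,
    er_interpolation = "linear",
    roc = curve
  ), class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("Screening evaluation (", x$n_active, " actives / ", x$n_decoy,
      " decoys, aggregation: ", x$method, ")\n", sep = "")
  cat("  AUC      ", format(x$auc, digits = 4), "\n")
  cat("  ER ", format(100 * x$fpr_level), "%   ", format(x$er, digits = 4),
      "\n", sep = "")
  cat("  top-", x$top_n, " hits ", x$top_hits, "\n", sep = "")
  invisible(x)
}
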