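# Differential-expression screen: per-feature fold change + t-test,
# threshold classification, screen summaries, gene-set intersection,
# hypergeometric enrichment, degree-based hub ranking.

#' Screen thresholds
#'
#' @param fc_up upper fold-change bound: features with \code{fc > fc_up} (and
#'   a passing p-value) are classified \code{up}.
#' @param fc_down lower bound: \code{fc < fc_down} classifies \code{down}.
#'   Must satisfy \code{fc_down < 1 < fc_up}. The bounds are taken literally as
#'   printed in the field's screens (0.9 is not 1/1.1) rather than symmetrized.
#' @param alpha significance level.
#' @param p_mode \code{"raw"} uses the unadjusted p; \code{"bh_adjusted"} uses
#'   the Benjamini-Hochberg adjusted p.
#' @return a validated list of class \code{screen_thresholds}.
#' @seealso \code{\link{screen_preset}} for the standard proteomic /
#'   phosphoproteomic / transcriptomic settings.
#' @export
screen_thresholds <- function(fc_up = 1.1, fc_down = 0.9, alpha = 0.05,
                              p_mode = c("raw", "bh_adjusted")) {
  check_scalar(fc_up, "fc_up", positive = TRUE)
  check_scalar(fc_down, "fc_down", positive = TRUE)
  if (!(fc_down < 1 && 1 < fc_up)) param_error("need fc_down < 1 < fc_up")
  check_scalar(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) param_error("'alpha' must be in (0, 1)")
  p_mode <- match.arg(p_mode)
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 p_mode = p_mode),
            class = "screen_thresholds")
}

#' Standard threshold presets
#'
#' \code{"proteomic"}: FC > 1.1 up / FC < 0.9 down, raw P < 0.05.
#' \code{"phospho"}: FC > 1.2 / FC < 0.83, raw P < 0.05.
#' \code{"transcript"}: FC > 1.2 / FC < 0.83, BH-adjusted P < 0.01 — a generic
#' stand-in for count-model DEG calling (this package does not implement a
#' negative-binomial model; see the methods vignette).
#'
#' @param preset preset name.
#' @return a \code{\link{screen_thresholds}} object.
#' @export
screen_preset <- function(preset = c("proteomic", "phospho", "transcript")) {
  switch(match.arg(preset),
         proteomic = screen_thresholds(1.1, 0.9, 0.05, "raw"),
         phospho = screen_thresholds(1.2, 0.83, 0.05, "raw"),
         transcript = screen_thresholds(1.2, 0.83, 0.01, "bh_adjusted"))
}

#' Per-feature fold change and t-test
#'
#' Fold change is the raw (unlogged) ratio of treatment-group mean to
#' control-group mean. P-values come from a two-sided two-sample t-test,
#' pooled-variance Student's form by default (\code{var_equal = FALSE} gives
#' Welch). Benjamini-Hochberg adjustment is applied across all features.
#' Features with zero variance in both groups get \code{p = 1} when the means
#' are equal and \code{p = 0} otherwise, flagged in the \code{degenerate}
#' column.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param var_equal pooled-variance Student's t (default) vs Welch.
#' @return data.frame with columns \code{feature_id}, \code{mean_ctrl},
#'   \code{mean_trt}, \code{fc}, \code{p}, \code{p_adj}, \code{degenerate},
#'   \code{cls} (\code{NA} until \code{\link{classify_features}}).
#' @export
compute_feature_stats <- function(table, var_equal = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  ctrl <- table$values[, table$groups == "control", drop = FALSE]
  trt <- table$values[, table$groups == "treatment", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(trt)
  v1 <- apply(ctrl, 1L, stats::var); v2 <- apply(trt, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = table$feature_ids,
             mean_ctrl = m1, mean_trt = m2, fc = m2 / m1,
             p = p, p_adj = p_adj, degenerate = degenerate,
             cls = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify features against screen thresholds
#'
#' \code{up} iff \code{fc > fc_up} and \code{p* < alpha}; \code{down} iff
#' \code{fc < fc_down} and \code{p* < alpha}; otherwise \code{ns}, where
#' \code{p*} is the raw or BH-adjusted p per the threshold's \code{p_mode}.
#'
#' @param stats a \code{\link{compute_feature_stats}} result.
#' @param thr a \code{\link{screen_thresholds}} object (or preset name).
#' @return \code{stats} with the \code{cls} column filled in.
#' @export
classify_features <- function(stats, thr = screen_preset("proteomic")) {
  if (is.character(thr)) thr <- screen_preset(thr)
  stopifnot(inherits(thr, "screen_thresholds"))
  pstar <- if (thr$p_mode == "raw") stats$p else stats$p_adj
  cls <- rep("ns", nrow(stats))
  cls[stats$fc > thr$fc_up & pstar < thr$alpha] <- "up"
  cls[stats$fc < thr$fc_down & pstar < thr$alpha] <- "down"
  stats$cls <- cls
  stats
}

#' Summarize a screen: DEP counts and percentages
#'
#' Percentages are \code{100 * count / n_identified} rounded half-away-from-
#' zero to 2 decimals; \code{n_total_dep = n_up + n_down}.
#'
#' @param x either a classified stats data.frame (counts derived from its
#'   \code{cls} column, \code{n_identified = nrow}), or the explicit count
#'   \code{n_identified} when \code{n_up}/\code{n_down} are given.
#' @param n_up,n_down explicit counts (used when \code{x} is a number).
#' @return an object of class \code{screen_summary}: list with
#'   \code{n_identified}, \code{n_up}, \code{n_down}, \code{n_total_dep},
#'   \code{pct_up}, \code{pct_down}.
#' @export
#' @examples
#' summarize_screen(7190, n_up = 157, n_down = 114)
summarize_screen <- function(x, n_up = NULL, n_down = NULL) {
  if (is.data.frame(x)) {
    n_identified <- nrow(x)
    n_up <- sum(x$cls == "up", na.rm = TRUE)
    n_down <- sum(x$cls == "down", na.rm = TRUE)
  } else {
    check_scalar(x, "n_identified", positive = TRUE)
    n_identified <- x
    check_scalar(n_up, "n_up", nonneg = TRUE)
    check_scalar(n_down, "n_down", nonneg = TRUE)
  }
  if (n_up + n_down > n_identified) {
    param_error("n_up + n_down exceeds n_identified")
  }
  structure(list(n_identified = n_identified, n_up = n_up, n_down = n_down,
                 n_total_dep = n_up + n_down,
                 pct_up = round_half_away(100 * n_up / n_identified, 2L),
                 pct_down = round_half_away(100 * n_down / n_identified, 2L)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen_summary: %d identified; %d up (%.2f%%), %d down (%.2f%%); %d DEPs total\n",
              x$n_identified, x$n_up, x$pct_up, x$n_down, x$pct_down,
              x$n_total_dep))
  invisible(x)
}

#' Intersect a query id list with a reference gene set
#'
#' Both sides are normalized with \code{\link{normalize_ids}} before the exact
#' set intersection.
#'
#' @param query character vector of identifiers (e.g. DEG ids).
#' @param reference a \code{\link{gene_set}} or character vector.
#' @return list with \code{ids} (sorted overlap) and \code{count}.
#' @export
intersect_gene_sets <- function(query, reference) {
  ref_ids <- if (inherits(reference, "gene_set")) reference$ids else
    unique(normalize_ids(reference))
  q <- unique(normalize_ids(query))
  ids <- sort(intersect(q, ref_ids))
  list(ids = ids, count = length(ids))
}

#' Hypergeometric enrichment of a gene set among differential features
#'
#' With \code{N} detected background features, \code{M} of them annotated to
#' the pathway, and \code{n} differential features, the overlap \code{k} is
#' tested against the upper-tail hypergeometric probability
#' \code{P(X >= k) = sum_{i=k}^{min(M,n)} C(M,i) C(N-M,n-i) / C(N,n)}.
#' The enrichment factor is \code{k/M}: the fraction of detected pathway
#' members that are differential (0 when \code{M = 0}, flagged).
#'
#' @param dep_ids differential feature ids (must be a subset of background
#'   after normalization).
#' @param pathway a \code{\link{gene_set}} or character vector; intersected
#'   with the background first.
#' @param background detected background ids.
#' @return an object of class \code{enrichment_result}: list with
#'   \code{pathway}, \code{k}, \code{M}, \code{n}, \code{N},
#'   \code{enrichment_factor}, \code{p_hyper}, \code{overlap_ids},
#'   \code{empty_pathway} flag.
#' @export
enrichment_test <- function(dep_ids, pathway, background) {
  pw_name <- if (inherits(pathway, "gene_set")) pathway$name else "pathway"
  pw_ids <- if (inherits(pathway, "gene_set")) pathway$ids else
    unique(normalize_ids(pathway))
  dep <- unique(normalize_ids(dep_ids))
  bg <- unique(normalize_ids(background))
  extra <- setdiff(dep, bg)
  if (length(extra)) {
    data_error("%d differential id(s) not in background (e.g. %s)",
               length(extra), extra[1L])
  }
  pw <- intersect(pw_ids, bg)
  M <- length(pw)
  n <- length(dep)
  N <- length(bg)
  overlap <- sort(intersect(dep, pw))
  k <- length(overlap)
  p <- stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
  structure(list(pathway = pw_name, k = k, M = M, n = n, N = N,
                 enrichment_factor = if (M == 0) 0 else k / M,
                 p_hyper = min(max(p, 0), 1),
                 overlap_ids = overlap, empty_pathway = M == 0),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result [%s]: k=%d of M=%d pathway members among n=%d differential (N=%d); factor %.4f, P = %.4g\n",
              x$pathway, x$k, x$M, x$n, x$N, x$enrichment_factor, x$p_hyper))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' Nodes are ranked by degree descending with lexicographic tie-breaking. The
#' default \code{top_k = 9} mirrors the usual "key hub genes" report size in
#' PPI screens; requests beyond the node count are truncated with a warning.
#'
#' @param network an \code{\link{interaction_network}}.
#' @param top_k number of top nodes to return.
#' @return data.frame of class \code{hub_ranking} with columns \code{id},
#'   \code{degree}, ordered by rank.
#' @export
rank_hubs <- function(network, top_k = 9) {
  stopifnot(inherits(network, "interaction_network"))
  check_scalar(top_k, "top_k", positive = TRUE)
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  tab <- table(c(network$edges$from, network$edges$to))
  deg[names(tab)] <- as.integer(tab)
  o <- order(-deg, names(deg))
  if (top_k > length(deg)) {
    warning(sprintf("top_k = %d exceeds node count %d; truncating",
                    top_k, length(deg)))
    top_k <- length(deg)
  }
  sel <- o[seq_len(top_k)]
  structure(data.frame(id = names(deg)[sel], degree = unname(deg[sel]),
                       stringsAsFactors = FALSE),
            class = c("hub_ranking", "data.frame"))
}
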