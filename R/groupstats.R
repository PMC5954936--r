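#' Edge-wise network comparison with permutation p-values and FDR control
#'
#' Network-based statistics in FDR mode: every off-diagonal edge weight is
#' compared between groups with a two-sample pooled-variance t statistic,
#' the per-edge null distribution is built by randomly relabelling group
#' membership `n_permutations` times (the observed labelling counts toward
#' the null: p = (1 + #{|t_perm| >= |t_obs|}) / (n_permutations + 1)), and
#' Benjamini-Hochberg FDR at `alpha_level` over all off-diagonal edges
#' yields the significant-edge mask. Edges with zero variance in both
#' groups have an undefined t and are assigned p = 1.
#'
#' @param group_a,group_b Lists of k x k adjacency matrices (or
#'   `connectivity_matrix` objects), one per subject.
#' @param alpha_level FDR level (default 0.05).
#' @param n_permutations Number of relabelling permutations (50,000 in the
#'   full analysis profile).
#' @param seed Integer seed for the permutations.
#' @return Object of class `edge_comparison`: `t_stats`, `perm_p`,
#'   `fdr_p` (BH-adjusted), `fdr_mask`, `direction` (+1 where group A
#'   larger), `n_permutations`, `alpha_level`, `seed`.
#' @export
nbs_fdr <- function(group_a, group_b, alpha_level = 0.05,
                    n_permutations = 5000, seed = 1) {
  to_mat <- function(x) as_adjacency(x)
  a <- lapply(group_a, to_mat); b <- lapply(group_b, to_mat)
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("need at least 2 networks per group")
  k <- nrow(a[[1]])
  if (any(vapply(c(a, b), nrow, 1L) != k))
    stop_invalid("all networks must share the same node set")
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1)
  alpha_level <- check_fraction(alpha_level, "alpha_level")
  off <- which(row(diag(k)) != col(diag(k)))        # off-diagonal linear idx
  dat <- rbind(t(vapply(a, function(m) m[off], numeric(length(off)))),
               t(vapply(b, function(m) m[off], numeric(length(off)))))
  na <- length(a); nb <- length(b); n <- na + nb

  tstat <- function(lab_a) {
    xa <- dat[lab_a, , drop = FALSE]; xb <- dat[!lab_a, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
    sp <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    se <- sqrt(sp * (1 / na + 1 / nb))
    t <- (ma - mb) / se
    t[se == 0] <- 0                                  # zero-variance edges
    t
  }
  obs_lab <- rep(c(TRUE, FALSE), c(na, nb))
  t_obs <- tstat(obs_lab)
  exceed <- rep(1L, length(off))                     # observed labelling counts
  perm_seeds <- derive_seeds(seed, n_permutations)
  for (p in seq_len(n_permutations)) {
    lab <- with_seed(perm_seeds[p], sample(obs_lab))
    exceed <- exceed + (abs(tstat(lab)) >= abs(t_obs))
  }
  perm_p <- exceed / (n_permutations + 1)
  zero_var <- apply(dat, 2, stats::var) == 0
  perm_p[zero_var] <- 1
  fdr_p <- stats::p.adjust(perm_p, method = "BH")
  as_k <- function(v, fill = 0) {
    m <- matrix(fill, k, k); m[off] <- v; m
  }
  structure(
    list(t_stats = as_k(t_obs), perm_p = as_k(perm_p, fill = 1),
         fdr_p = as_k(fdr_p, fill = 1),
         fdr_mask = as_k(fdr_p <= alpha_level) > 0,
         direction = as_k(sign(t_obs)),
         n_permutations = n_permutations, alpha_level = alpha_level,
         seed = seed, n_zero_variance = sum(zero_var)),
    class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf("<edge_comparison> %d node(s), %d significant edge(s) at FDR %.3g (%d permutations)\n",
              nrow(x$t_stats), sum(x$fdr_mask), x$alpha_level, x$n_permutations))
  invisible(x)
}

#' Normality-gated comparison of a scalar network property
#'
#' Shapiro-Wilk is applied to each sample (to the paired differences when
#' `paired = TRUE`); if normality is not rejected at 0.05 in either sample,
#' a t-test (paired or independent) is used, otherwise the Wilcoxon
#' signed-rank (paired) or Mann-Whitney U (independent) test. A
#' Kolmogorov-Smirnov normality check is computed and recorded for
#' reference but does not drive the branch. Constant samples make the
#' normality test undefined and fall to the nonparametric branch with a
#' note.
#'
#' @param sample_a,sample_b Numeric vectors (>= 3 values each; equal
#'   lengths when paired).
#' @param paired Paired design flag.
#' @param alpha_level Significance level recorded on the result.
#' @return Object of class `property_comparison` with the gate diagnostics,
#'   chosen test, statistic, p-value and group summaries.
#' @export
compare_property <- function(sample_a, sample_b, paired = FALSE,
                             alpha_level = 0.05) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop_invalid("need >= 3 values per sample")
  if (paired && length(sample_a) != length(sample_b))
    stop_invalid("paired samples must have equal length")
  safe_sw <- function(x) {
    if (stats::sd(x) == 0 || length(unique(x)) < 3) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  safe_ks <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test(scale(x), "pnorm")$p.value)
  }
  sw <- c(a = safe_sw(sample_a), b = safe_sw(sample_b))
  ks <- c(a = safe_ks(sample_a), b = safe_ks(sample_b))
  note <- NULL
  if (paired && all(sample_a == sample_b)) {
    # identical paired samples: zero statistic, maximal p
    return(structure(
      list(test_used = "paired_t", statistic = 0, p_value = 1,
           normality_p = sw, ks_p = ks, alpha_level = alpha_level,
           paired = TRUE,
           note = "paired samples are identical; maximal p reported",
           summary = data.frame(
             group = c("a", "b"),
             mean = c(mean(sample_a), mean(sample_b)),
             median = c(stats::median(sample_a), stats::median(sample_b)),
             sd = c(stats::sd(sample_a), stats::sd(sample_b)))),
      class = "property_comparison"))
  }
  if (paired && stats::sd(sample_a - sample_b) == 0) {
    # constant nonzero difference: t undefined, use the signed-rank branch
    note <- "paired differences are constant; nonparametric branch used"
    sw[] <- NA_real_
  }
  if (anyNA(sw)) {
    normal <- FALSE
    if (is.null(note))
      note <- "normality undefined for a constant sample; nonparametric branch used"
  } else {
    normal <- all(sw > 0.05)
  }
  if (normal) {
    test_used <- if (paired) "paired_t" else "t"
    ht <- stats::t.test(sample_a, sample_b, paired = paired, var.equal = !paired)
  } else if (paired) {
    test_used <- "wilcoxon"
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, paired = TRUE,
                                              exact = FALSE))
  } else {
    test_used <- "mann_whitney"
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = FALSE))
  }
  structure(
    list(test_used = test_used, statistic = unname(ht$statistic),
         p_value = ht$p.value, normality_p = sw, ks_p = ks,
         alpha_level = alpha_level, paired = paired, note = note,
         summary = data.frame(
           group = c("a", "b"),
           mean = c(mean(sample_a), mean(sample_b)),
           median = c(stats::median(sample_a), stats::median(sample_b)),
           sd = c(stats::sd(sample_a), stats::sd(sample_b)))),
    class = "property_comparison")
}

#' @export
print.property_comparison <- function(x, ...) {
  cat(sprintf("<property_comparison> %s: statistic = %.4g, p = %.4g%s\n",
              x$test_used, x$statistic, x$p_value,
              if (is.null(x$note)) "" else paste0(" (", x$note, ")")))
  invisible(x)
}

#' Correlation of strength-difference trends between two nodes
#'
#' Pearson or Spearman correlation of per-category between-group strength
#' differences; `method = "auto"` selects Pearson when both vectors pass
#' Shapiro-Wilk at 0.05 and Spearman otherwise.
#'
#' @param diff_a,diff_b Equal-length numeric vectors (>= 3).
#' @param method `"pearson"`, `"spearman"`, or `"auto"`.
#' @return List with `r`, `p`, `method`; `r` is NA with a note when either
#'   vector has zero variance.
#' @export
strength_trend <- function(diff_a, diff_b, method = c("auto", "pearson",
                                                      "spearman")) {
  method <- match.arg(method)
  diff_a <- as.numeric(diff_a); diff_b <- as.numeric(diff_b)
  if (length(diff_a) != length(diff_b) || length(diff_a) < 3)
    stop_invalid("need equal-length vectors of >= 3 values")
  if (stats::sd(diff_a) == 0 || stats::sd(diff_b) == 0)
    return(list(r = NA_real_, p = NA_real_, method = method,
                note = "zero-variance input: correlation undefined"))
  if (method == "auto") {
    sw <- function(x) tryCatch(stats::shapiro.test(x)$p.value,
                               error = function(e) 0)
    method <- if (sw(diff_a) > 0.05 && sw(diff_b) > 0.05) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(diff_a, diff_b, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Average per-task results over imagery categories
#'
#' Each category's value is the arithmetic mean over its member tasks; a
#' task contributes to every category it belongs to (the taxonomy is
#' overlapping: an arm task is simultaneously in Hands, a laterality, a
#' proximity and a motion category), and Walking contains only the walking
#' task. Categories with no measured member task are reported as NA, not
#' zero.
#'
#' @param values Named numeric vector (or named list of numbers/matrices)
#'   keyed by task_id.
#' @param categories Named list mapping each task_id to its category label
#'   vector; defaults to the built-in taxonomy via [task_categories()].
#' @param category_levels Categories to report (default the 8 imagery
#'   categories).
#' @return Named list of per-category means (numeric or matrix, matching
#'   the element type of `values`).
#' @export
aggregate_by_category <- function(values, categories = NULL,
                                  category_levels = c("Hands", "Left", "Right",
                                                      "Proximal", "Distal",
                                                      "Rotational", "Linear",
                                                      "Walking")) {
  ids <- names(values)
  if (is.null(ids)) stop_invalid("`values` must be named by task_id")
  if (is.null(categories))
    categories <- stats::setNames(lapply(ids, task_categories), ids)
  if (!all(ids %in% names(categories)))
    stop_invalid("missing category labels for: %s",
                 paste(setdiff(ids, names(categories)), collapse = ", "))
  out <- stats::setNames(vector("list", length(category_levels)), category_levels)
  for (cat in category_levels) {
    members <- ids[vapply(ids, function(id) cat %in% categories[[id]], logical(1))]
    if (!length(members)) {
      out[[cat]] <- NA_real_
      next
    }
    vals <- if (is.list(values)) values[members] else as.list(values[members])
    out[[cat]] <- Reduce(`+`, vals) / length(vals)
  }
  if (all(vapply(out, function(v) is.numeric(v) && length(v) == 1, logical(1))))
    unlist(out)
  else out
}
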