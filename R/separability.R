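#' Assemble the five-feature matrix for cluster analysis
#'
#' Binds assigned responses (rows) into the feature space used for the
#' separability analysis: amplitude, duration, rise slope, decay slope and
#' integral, with each row labelled by its cytokine group and condition.
#' Censored responses and rows with missing features are dropped.
#'
#' @param responses Response table from [assign_responses()] (must carry a
#'   `stimulus` column).
#' @param condition Condition label for these rows (recycled), or a vector.
#' @param include_censored Keep censored rows (default FALSE).
#' @return Data.frame with the five feature columns plus `group` and
#'   `condition`.
#' @export
assemble_feature_matrix <- function(responses, condition,
                                    include_censored = FALSE) {
  if (!nrow(responses)) stopf("no responses to assemble")
  keep <- rep(TRUE, nrow(responses))
  if (!include_censored && "censored" %in% names(responses))
    keep <- keep & !responses$censored
  df <- responses[keep, , drop = FALSE]
  out <- df[, .features, drop = FALSE]
  out$group <- df$stimulus
  out$condition <- rep_len(as.character(condition), nrow(out))
  out <- out[stats::complete.cases(out[, .features]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tukey-fence outlier filter
#'
#' Flags rows whose features fall outside `[Q1 - k*IQR, Q3 + k*IQR]`,
#' computed per feature within each cytokine-by-condition group (responses to
#' different cytokines live on different scales, so fences are never pooled).
#' Quartiles use linear interpolation at index `(n-1)q` of the sorted sample.
#' A row is removed when ANY of its features is outside its group's fence;
#' values exactly on a degenerate fence (IQR = 0) are kept. Groups with fewer
#' than 4 rows are passed through unfiltered with a warning.
#'
#' @param fm Feature data.frame from [assemble_feature_matrix()].
#' @param k Fence multiplier (default 1.5).
#' @return Logical keep-mask over the rows of `fm`.
#' @export
tukey_fence_filter <- function(fm, k = 1.5) {
  keep <- rep(TRUE, nrow(fm))
  cells <- interaction(fm$group, fm$condition, drop = TRUE)
  for (cell in levels(cells)) {
    rows <- which(cells == cell)
    if (length(rows) < 4L) {
      warnf("group '%s' has fewer than 4 rows; passed through unfiltered",
            cell)
      next
    }
    for (f in .features) {
      v <- fm[[f]][rows]
      qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- qs[2L] - qs[1L]
      out <- v < qs[1L] - k * iqr | v > qs[2L] + k * iqr
      keep[rows[out]] <- FALSE
    }
  }
  keep
}

#' Z-score the feature columns
#'
#' Per-column standardisation over all (pooled) rows, so Euclidean distances
#' weigh the heterogeneous feature units (%DFF, s, %DFF/s, %DFF*s)
#' comparably. Uses the sample (n-1) SD convention.
#'
#' @param x Numeric matrix or data.frame of feature columns.
#' @return Numeric matrix of z-scores.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("feature columns must be numeric")
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stopf("feature '%s' has zero spread and cannot be standardised",
          colnames(x)[zero[1L]] %||% as.character(zero[1L]))
  sweep(sweep(x, 2L, mu), 2L, sds, "/")
}

#' Iterative cross-group nearest-neighbor pruning
#'
#' Removes the points most responsible for overlap between cytokine groups:
#' repeatedly (ceiling(drop_fraction * n0) times) compute, for every
#' surviving point, the Euclidean distance to its nearest surviving neighbor
#' in a DIFFERENT group, and delete the single point with the smallest such
#' distance. Ties go to the lexicographically smaller group label, then the
#' lower row index, making the procedure fully deterministic. If a group
#' would be emptied before the quota is met, pruning stops early with a
#' warning.
#'
#' @param x Numeric matrix of (standardised) feature rows.
#' @param groups Group label per row (>= 2 distinct labels).
#' @param drop_fraction Fraction of the starting rows to remove, in `[0, 1)`.
#' @return Logical keep-mask over the rows.
#' @export
iterative_nn_prune <- function(x, groups, drop_fraction = 0.25) {
  x <- as.matrix(x)
  n <- nrow(x)
  groups <- as.character(groups)
  if (length(groups) != n) stopf("groups must match the number of rows")
  if (length(unique(groups)) < 2L) stopf("need at least 2 groups")
  if (drop_fraction < 0 || drop_fraction >= 1)
    stopf("drop_fraction must be in [0, 1)")
  quota <- ceiling(drop_fraction * n)
  keep <- rep(TRUE, n)
  if (quota == 0L) return(keep)

  D <- as.matrix(stats::dist(x))
  same <- outer(groups, groups, "==")
  D[same] <- Inf
  diag(D) <- Inf

  nn_d <- apply(D, 1L, min)
  nn_i <- apply(D, 1L, which.min)

  for (step in seq_len(quota)) {
    alive <- which(keep)
    d_alive <- nn_d[alive]
    best <- min(d_alive)
    cand <- alive[d_alive == best]
    if (length(cand) > 1L) cand <- cand[order(groups[cand], cand)]
    r <- cand[1L]
    keep[r] <- FALSE
    if (!any(keep & groups == groups[r])) {
      warnf("group '%s' emptied after %d removals; pruning stopped early",
            groups[r], step)
      break
    }
    # refresh points whose nearest cross-group neighbor was the removed row
    stale <- which(keep & nn_i == r)
    for (i in stale) {
      row <- D[i, ]
      row[!keep] <- Inf
      nn_i[i] <- which.min(row)
      nn_d[i] <- row[nn_i[i]]
      if (!is.finite(nn_d[i])) {
        warnf("no cross-group neighbors left; pruning stopped early")
        return(keep)
      }
    }
  }
  keep
}

#' Calinski-Harabasz cluster validity index
#'
#' CH = (B / (k - 1)) / (W / (n - k)), where B is the between-group
#' dispersion (group sizes times squared distances of group means from the
#' grand mean) and W the pooled within-group dispersion. Higher values mean
#' better-separated, tighter clusters. W = 0 with B > 0 yields `Inf`
#' (noise-free synthetic fixtures stay usable); identical group means yield
#' 0.
#'
#' @param x Numeric matrix (rows = points) or vector (1-D points).
#' @param groups Group label per row; at least 2 groups, and more points than
#'   groups.
#' @return The CH value (>= 0, possibly `Inf`).
#' @examples
#' calinski_harabasz(c(0, 1, 10, 11), c("a", "a", "b", "b"))  # 200
#' @export
calinski_harabasz <- function(x, groups) {
  x <- as.matrix(x)
  g <- factor(groups)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  if (nrow(x) <= nlevels(g)) stopf("need more points than groups")
  if (nrow(x) != length(g)) stopf("groups must match the number of rows")
  ch_index_cpp(x, as.integer(g), nlevels(g))
}

# Mann-Whitney U statistic for sample x against y (midranks for ties)
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Stratified subsample index sets: S sets, each taking m rows per group
draw_subsample_idx <- function(rows_by_group, S, m) {
  lapply(seq_len(S), function(s) {
    unlist(lapply(rows_by_group, function(rows) {
      if (length(rows) == 1L) rep(rows, m) else sample(rows, m)
    }), use.names = FALSE)
  })
}

#' Permutative Mann-Whitney comparison of cluster separability
#'
#' Turns the single Calinski-Harabasz value per condition into a testable
#' sample: for each condition, draw `S` stratified subsamples (`m` rows per
#' cytokine group, without replacement within a subsample) and compute CH on
#' each, giving two samples of `S` CH values compared with a Mann-Whitney U
#' statistic. The null distribution comes from `P` permutations that shuffle
#' condition labels across rows within each cytokine stratum and recompute
#' both CH samples and U; the two-sided p-value is
#' `(1 + n_exceed) / (1 + P)`, where `n_exceed` counts permutations with
#' `|U_perm - EU| >= |U_obs - EU|`. Headline CH values
#' per condition are computed once on all supplied rows.
#'
#' @param x Numeric matrix of (standardised, pruned) feature rows.
#' @param groups Cytokine group label per row.
#' @param condition Condition label per row (exactly 2 levels).
#' @param S Number of subsamples per condition.
#' @param m Rows per group per subsample; default 80\% of the smallest
#'   group-by-condition cell, capped at 12 (and at least 2). Subsample sizes
#'   near the cell size make consecutive subsamples nearly identical, which
#'   collapses the spread of the CH sample and degenerates the U statistic
#'   (it saturates for permuted label splits too); a moderate `m` preserves
#'   power.
#' @param P Number of permutations.
#' @param seed RNG seed for subsampling and permutation.
#' @return An object of class `separability_result`: list with `ch`
#'   (named per-condition headline CH), `u_statistic`, `p_value`,
#'   `ch_samples`, `n_kept` (group-by-condition counts), and `params`.
#' @export
permutative_mann_whitney <- function(x, groups, condition, S = 50, m = NULL,
                                     P = 2000, seed = 1L) {
  x <- as.matrix(x)
  g <- factor(groups)
  cond <- factor(condition)
  if (nlevels(cond) != 2L) stopf("exactly 2 conditions are required")
  if (nlevels(g) < 2L) stopf("need at least 2 cytokine groups")
  k <- nlevels(g)

  counts <- table(g, cond)
  # Default m: 80% of the smallest group-by-condition cell, capped at 12.
  # As m approaches the cell size the subsamples coincide, the within-
  # condition spread of the CH sample collapses, and U saturates for the
  # permuted halves as well as the observed split -- the test degenerates.
  # A moderate m keeps the CH sample informative.
  if (is.null(m)) m <- max(2L, min(12L, floor(0.8 * min(counts))))
  if (any(counts < m))
    stopf("insufficient rows: need at least m = %d per cytokine group per condition (smallest cell has %d)",
          m, min(counts))

  lev <- levels(cond)
  glab <- rep(seq_len(k), each = m)    # group labels of stacked subsample rows

  with_seed(seed, {
    rows_by <- function(cond_rows)
      lapply(levels(g), function(gl) cond_rows[g[cond_rows] == gl])
    ch_sample <- function(cond_rows) {
      idx <- draw_subsample_idx(rows_by(cond_rows), S, m)
      ch_subsets_cpp(x, idx, glab, k)
    }

    rows1 <- which(cond == lev[1L])
    rows2 <- which(cond == lev[2L])
    ch1 <- ch_sample(rows1)
    ch2 <- ch_sample(rows2)
    u_obs <- mann_whitney_u(ch1, ch2)
    eu <- S * S / 2
    dev_obs <- abs(u_obs - eu)

    n_exceed <- 0L
    strata <- lapply(levels(g), function(gl) which(g == gl))
    n1_by <- vapply(strata, function(rows) sum(cond[rows] == lev[1L]),
                    integer(1))
    for (p in seq_len(P)) {
      p1 <- integer(0); p2 <- integer(0)
      for (si in seq_along(strata)) {
        perm <- sample(strata[[si]])
        p1 <- c(p1, perm[seq_len(n1_by[si])])
        p2 <- c(p2, perm[-seq_len(n1_by[si])])
      }
      u_p <- mann_whitney_u(ch_sample(p1), ch_sample(p2))
      if (abs(u_p - eu) >= dev_obs) n_exceed <- n_exceed + 1L
    }

    ch_all <- vapply(lev, function(l) {
      rows <- which(cond == l)
      calinski_harabasz(x[rows, , drop = FALSE], g[rows])
    }, numeric(1))

    structure(
      list(ch = ch_all, u_statistic = u_obs,
           p_value = (1 + n_exceed) / (1 + P),
           ch_samples = stats::setNames(list(ch1, ch2), lev),
           n_kept = counts,
           params = list(S = S, m = m, P = P, seed = seed)),
      class = "separability_result")
  })
}

#' Full cluster-separability analysis
#'
#' Runs the complete procedure on an assembled feature matrix: per
#' cytokine-by-condition Tukey-fence outlier removal, pooled z-scoring,
#' per-condition iterative cross-group nearest-neighbor pruning, headline
#' Calinski-Harabasz indices per condition, and the permutative Mann-Whitney
#' comparison between conditions.
#'
#' @param fm Feature data.frame from [assemble_feature_matrix()] (both
#'   conditions bound together).
#' @param fence_k Tukey fence multiplier.
#' @param drop_fraction Fraction pruned per condition.
#' @param standardize Z-score features before distances (default TRUE).
#' @param S,m,P,seed Passed to [permutative_mann_whitney()].
#' @return A `separability_result` with, additionally, `masks` (fence and
#'   prune keep-masks over the input rows), `kept` (the pruned standardised
#'   matrix with group/condition), and `n_steps` (row counts after each
#'   step).
#' @export
separability_analysis <- function(fm, fence_k = 1.5, drop_fraction = 0.25,
                                  standardize = TRUE, S = 50, m = NULL,
                                  P = 2000, seed = 1L) {
  stopifnot(all(c(.features, "group", "condition") %in% names(fm)))
  fence_keep <- tukey_fence_filter(fm, k = fence_k)
  kept1 <- fm[fence_keep, , drop = FALSE]

  xs <- as.matrix(kept1[, .features])
  if (standardize) xs <- standardize_features(xs)

  prune_keep <- rep(TRUE, nrow(kept1))
  for (l in unique(kept1$condition)) {
    rows <- which(kept1$condition == l)
    prune_keep[rows] <- iterative_nn_prune(xs[rows, , drop = FALSE],
                                           kept1$group[rows], drop_fraction)
  }

  x2 <- xs[prune_keep, , drop = FALSE]
  g2 <- kept1$group[prune_keep]
  c2 <- kept1$condition[prune_keep]

  res <- permutative_mann_whitney(x2, g2, c2, S = S, m = m, P = P, seed = seed)
  res$masks <- list(fence = fence_keep, prune = prune_keep)
  res$kept <- data.frame(x2, group = g2, condition = c2,
                         stringsAsFactors = FALSE)
  res$n_steps <- c(input = nrow(fm), after_fence = nrow(kept1),
                   after_prune = nrow(x2))
  res$params <- c(res$params,
                  list(fence_k = fence_k, drop_fraction = drop_fraction,
                       standardize = standardize))
  res
}

#' @export
print.separability_result <- function(x, ...) {
  cat("<separability_result>\n")
  cat(sprintf("  CH %s\n",
              paste(sprintf("%s = %.2f", names(x$ch), x$ch),
                    collapse = " vs ")))
  cat(sprintf("  permutative Mann-Whitney: U = %.1f, p = %.4g (S = %d, m = %d, P = %d)\n",
              x$u_statistic, x$p_value, x$params$S, x$params$m, x$params$P))
  if (!is.null(x$n_steps))
    cat(sprintf("  rows: %d input -> %d after fence -> %d after prune\n",
                x$n_steps["input"], x$n_steps["after_fence"],
                x$n_steps["after_prune"]))
  invisible(x)
}

#' Routine group comparisons on per-animal means
#'
#' The workhorse tests used alongside the clustering analysis: one-way ANOVA
#' with Tukey HSD adjusted pairwise comparisons across three or more groups,
#' and a two-sided Mann-Whitney U test when exactly two groups are compared
#' (exact p for small samples without ties, normal approximation with tie
#' correction otherwise). Groups with fewer than 2 values are excluded with a
#' warning.
#'
#' @param values Numeric vector of animal-level means.
#' @param groups Group label per value.
#' @return An object of class `group_tests`: list with `anova`
#'   (`F`, `p`), `tukey` (data.frame pair/diff/p_adj), and, for two groups,
#'   `mann_whitney` (`U`, `p`, `method`).
#' @export
group_tests <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warnf("excluding group(s) with n < 2: %s", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stopf("need at least 2 groups with n >= 2")

  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)

  mw <- NULL
  if (nlevels(g) == 2L) {
    x <- values[g == levels(g)[1L]]
    y <- values[g == levels(g)[2L]]
    exact <- min(length(x), length(y)) <= 8 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    mw <- list(U = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal approximation")
  }

  structure(list(anova = list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L]),
                 tukey = tukey, mann_whitney = mw,
                 groups = levels(g), n = as.integer(table(g))),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat("<group_tests>", paste(sprintf("%s (n=%d)", x$groups, x$n),
                             collapse = ", "), "\n")
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g\n", x$anova$F, x$anova$p))
  for (i in seq_len(nrow(x$tukey)))
    cat(sprintf("  Tukey %s: diff = %.3f, adj p = %.4g\n",
                x$tukey$pair[i], x$tukey$diff[i], x$tukey$p_adj[i]))
  if (!is.null(x$mann_whitney))
    cat(sprintf("  Mann-Whitney (%s): U = %g, p = %.4g\n",
                x$mann_whitney$method, x$mann_whitney$U, x$mann_whitney$p))
  invisible(x)
}
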