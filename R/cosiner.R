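#' Remove a gene's linear trend
#'
#' Fits an ordinary least-squares line f(t) = alpha*t + beta to the 24
#' observations and returns the residual series g' = g - f(t). Detrending
#' prevents a drifting baseline from being absorbed into (and distorting)
#' the cosine fit.
#'
#' @param g Numeric vector of 24 expression values.
#' @param grid The [diel_grid()].
#' @return List with `alpha` (per hour), `beta`, and `detrended` (length 24).
#' @export
detrend <- function(g, grid = diel_grid()) {
  .check_canonical_grid(grid)
  t <- grid$time
  if (length(g) != length(t) || any(!is.finite(g)))
    stop("'g' must hold ", length(t), " finite values")
  tc <- t - mean(t)
  alpha <- sum(tc * g) / sum(tc^2)
  beta <- mean(g) - alpha * mean(t)
  list(alpha = alpha, beta = beta, detrended = g - (alpha * t + beta))
}

#' Fit a cosine of fixed period to a detrended series
#'
#' Fourier-projection fit at trial period T:
#' \deqn{a = (2/n)\sum_i g'_i \cos(2\pi t_i/T), \quad
#'       b = (2/n)\sum_i g'_i \sin(2\pi t_i/T),}
#' model F(t) = sqrt(a^2+b^2) cos(2*pi*t/T - phi) with the acrophase
#' phi = atan2(b, a) wrapped to [0, 2*pi). The error factor
#' Ef = mean of (g' - F(t))^2 measures lack of fit; amplitude
#' 2*sqrt(a^2+b^2) is peak-to-trough; peak_time = 24*phi/(2*pi) expresses
#' the acrophase in circadian hours.
#'
#' @param gp Detrended series (24 values).
#' @param grid The [diel_grid()].
#' @param period Trial period T in hours (> 0).
#' @return A one-row data frame of class `"cosine_fit"`: `period`, `a`,
#'   `b`, `phi`, `ef`, `amplitude`, `peak_time`.
#' @examples
#' g <- cos(2 * pi * diel_grid()$time / 24)
#' fit_cosine(g, diel_grid(), 24)   # a = 1, b = 0, ef = 0
#' @export
fit_cosine <- function(gp, grid = diel_grid(), period) {
  .check_canonical_grid(grid)
  if (period <= 0) stop("'period' must be positive")
  scan <- .cosine_scan(matrix(gp, nrow = 1), grid$time, period)
  .fit_row(scan, 1L, 1L)
}

# Vectorized cosine projection of many genes over many trial periods.
# Returns matrices a, b, ef of dim n_genes x n_periods.
# Residual expansion avoids forming per-(gene, period) fitted series:
#   Ef = mean(gp^2) - (a^2 + b^2)
#        + (a^2*sum(C^2) + b^2*sum(S^2) + 2ab*sum(CS))/n
# using sum_i gp_i C_ij = (n/2) a_j (definition of a), likewise for b.
.cosine_scan <- function(G, t, periods) {
  n <- length(t)
  w <- outer(t, 2 * pi / periods)          # n x P phase angles
  C <- cos(w); S <- sin(w)
  a <- (2 / n) * (G %*% C)
  b <- (2 / n) * (G %*% S)
  cc <- colSums(C * C); ss <- colSums(S * S); cs <- colSums(C * S)
  m2 <- rowMeans(G * G)
  ef <- m2 - (a^2 + b^2) +
    (sweep(a^2, 2, cc, `*`) + sweep(b^2, 2, ss, `*`) + 2 * sweep(a * b, 2, cs, `*`)) / n
  ef[ef < 0] <- 0   # guard against cancellation at machine precision
  list(periods = periods, a = a, b = b, ef = ef)
}

.wrap_phi <- function(phi) {
  phi <- phi %% (2 * pi)
  # a negative angle of magnitude below machine epsilon wraps to 2*pi itself;
  # keep the contract phi in [0, 2*pi)
  phi[2 * pi - phi < 1e-12] <- 0
  phi
}

.fit_row <- function(scan, i, j) {
  a <- scan$a[i, j]; b <- scan$b[i, j]
  phi <- .wrap_phi(atan2(b, a))
  out <- data.frame(period = scan$periods[j], a = a, b = b, phi = phi,
                    ef = scan$ef[i, j], amplitude = 2 * sqrt(a^2 + b^2),
                    peak_time = 24 * phi / (2 * pi))
  class(out) <- c("cosine_fit", "data.frame")
  out
}

#' Default trial-period grid for rhythm fitting
#'
#' Periods from 12 to 36 h at 0.1-h steps (241 values), rounded to the
#' grid's nominal 0.1-h resolution so reported periods compare exactly.
#' @return Numeric vector of candidate periods.
#' @export
period_grid <- function() round(seq(12, 36, by = 0.1), 1)

#' Best-fitting cosine over a period grid
#'
#' Fits every trial period with [fit_cosine()]'s projection and returns the
#' fit with minimum error factor; ties go to the smallest period so output
#' is deterministic.
#'
#' @inheritParams fit_cosine
#' @param periods Ascending vector of trial periods (default [period_grid()]).
#' @return A `"cosine_fit"` row (see [fit_cosine()]).
#' @export
best_fit <- function(gp, grid = diel_grid(), periods = period_grid()) {
  if (!length(periods) || is.unsorted(periods))
    stop("'periods' must be a non-empty ascending vector")
  scan <- .cosine_scan(matrix(gp, nrow = 1), grid$time, periods)
  .fit_row(scan, 1L, which.min(scan$ef[1L, ]))  # which.min: first = smallest T
}

#' Peak-versus-trough Student t test
#'
#' Tests whether expression at the fitted curve's peak differs from the
#' trough. The peak clock hour is where the fitted cosine is maximal,
#' phi*T/(2*pi) mod 24; the trough sits half a period later. Each group
#' collects the observed values at the sampled label nearest that clock
#' hour plus its `k_labels - 1` neighbouring labels, in both cycles
#' (so `k_labels = 3` gives n = 6 per group). A two-sided pooled-variance
#' two-sample t test is applied; when both groups are constant the test is
#' undefined and p = 1 is returned by convention (p = 0 if the two constant
#' groups differ).
#'
#' @param g The 24 raw (or feature-scaled) values, not detrended.
#' @param fit A `"cosine_fit"` row for this gene.
#' @param grid The [diel_grid()].
#' @param k_labels Labels per group (odd; 3 = nearest plus both neighbours,
#'   1 = nearest only).
#' @return The raw two-sided p-value.
#' @export
peak_trough_test <- function(g, fit, grid = diel_grid(), k_labels = 3L) {
  .check_canonical_grid(grid)
  if (k_labels < 1L || k_labels %% 2L == 0L) stop("'k_labels' must be odd and >= 1")
  peak_hour <- (fit$phi * fit$period / (2 * pi)) %% 24
  trough_hour <- (peak_hour + fit$period / 2) %% 24
  group_vals <- function(hour) {
    d <- abs(grid$label_hours - hour)
    d <- pmin(d, 24 - d)                        # circular distance on the 24-h clock
    ctr <- which.min(d)
    idx <- ((ctr - 1L) + seq(-(k_labels %/% 2L), k_labels %/% 2L)) %% 12L + 1L
    g[grid$label %in% grid$label_levels[idx]]
  }
  peak <- group_vals(peak_hour)
  trough <- group_vals(trough_hour)
  if (stats::sd(peak) == 0 && stats::sd(trough) == 0)
    return(if (isTRUE(all.equal(mean(peak), mean(trough)))) 1 else 0)
  stats::t.test(peak, trough, var.equal = TRUE)$p.value
}

# Cycle-averaged 12-point profile and its argmax label (ties -> earliest
# label in D1..L11 order).
.cycle_average <- function(g, grid) {
  prof <- vapply(grid$label_levels, function(l) mean(g[grid$label == l]), numeric(1))
  names(prof) <- grid$label_levels
  prof
}

#' Classify genes as cyclic or non-cyclic
#'
#' Applies the full rhythm-detection procedure to a feature-scaled matrix:
#' per gene, detrend, scan the period grid for the minimum-Ef cosine, then
#' test three criteria hierarchically:
#' (i) fitted period within `period_window`;
#' (ii) error factor at most `ef_max`;
#' (iii) peak-versus-trough t test significant after Holm step-down
#' correction at level `alpha`, with the correction family restricted to
#' the genes that survived (i) and (ii).
#' A gene is cyclic iff all three hold. Each gene is also assigned the
#' sampled label at which its cycle-averaged 12-point profile is maximal.
#'
#' @param mat Feature-scaled gene x 24 matrix ([feature_scale()]).
#' @param grid The [diel_grid()].
#' @param periods Trial-period grid.
#' @param period_window Admissible period range in hours.
#' @param ef_max Error-factor ceiling.
#' @param alpha Family-wise significance level.
#' @param k_labels Passed to [peak_trough_test()].
#' @return A data frame of class `"rhythm_calls"`, one row per gene:
#'   `gene`, fit columns (`period`, `a`, `b`, `phi`, `amplitude`, `ef`,
#'   `peak_time`), criterion flags (`crit_period`, `crit_ef`, `crit_test`),
#'   `p_raw`, `p_adj` (NA outside the tested family), `is_cyclic`,
#'   `peak_label`.
#' @export
classify_rhythms <- function(mat, grid = diel_grid(), periods = period_grid(),
                             period_window = c(18, 26.8), ef_max = 0.2,
                             alpha = 0.05, k_labels = 3L) {
  if (!is_feature_scaled(mat))
    stop("'mat' must be feature-scaled (run feature_scale() first)")
  .check_canonical_grid(grid)
  n <- nrow(mat)
  genes <- rownames(mat)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n))

  t <- grid$time
  tc <- t - mean(t)
  alpha_hat <- (mat %*% tc) / sum(tc^2)
  beta_hat <- rowMeans(mat) - alpha_hat * mean(t)
  Gp <- mat - (alpha_hat %*% t(t) + beta_hat %*% t(rep(1, length(t))))

  scan <- .cosine_scan(Gp, t, periods)
  jbest <- apply(scan$ef, 1, which.min)
  pick <- cbind(seq_len(n), jbest)
  a <- scan$a[pick]; b <- scan$b[pick]; ef <- scan$ef[pick]
  period <- periods[jbest]
  phi <- .wrap_phi(atan2(b, a))

  crit_period <- period >= period_window[1] & period <= period_window[2]
  crit_ef <- ef <= ef_max
  family <- which(crit_period & crit_ef)

  p_raw <- rep(NA_real_, n)
  for (i in family) {
    fit <- data.frame(period = period[i], phi = phi[i])
    p_raw[i] <- peak_trough_test(mat[i, ], fit, grid, k_labels = k_labels)
  }
  p_adj <- rep(NA_real_, n)
  if (length(family)) p_adj[family] <- stats::p.adjust(p_raw[family], method = "holm")
  crit_test <- !is.na(p_adj) & p_adj < alpha
  is_cyclic <- crit_period & crit_ef & crit_test

  peak_label <- vapply(seq_len(n), function(i) {
    prof <- .cycle_average(mat[i, ], grid)
    grid$label_levels[which.max(prof)]   # which.max: earliest label wins ties
  }, character(1))

  out <- data.frame(gene = genes, period = period, a = a, b = b, phi = phi,
                    amplitude = 2 * sqrt(a^2 + b^2), ef = ef,
                    peak_time = 24 * phi / (2 * pi),
                    crit_period = crit_period, crit_ef = crit_ef,
                    p_raw = p_raw, p_adj = p_adj, crit_test = crit_test,
                    is_cyclic = is_cyclic, peak_label = peak_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("rhythm_calls", "data.frame")
  attr(out, "thresholds") <- list(period_window = period_window, ef_max = ef_max,
                                  alpha = alpha, k_labels = k_labels)
  out
}

#' Tabulate peak timepoints of cyclic genes by functional category
#'
#' @param calls A `"rhythm_calls"` data frame.
#' @param categories Optional data frame with columns `gene` and `category`
#'   (at most one category per gene); genes without an entry are counted
#'   under `"Unassigned and hypothetical"`.
#' @param grid The [diel_grid()] (supplies label order).
#' @return Integer matrix, categories x 12 peak labels, counting cyclic
#'   genes; row sums are the per-category cyclic gene totals.
#' @export
summarize_peaks <- function(calls, categories = NULL, grid = diel_grid()) {
  if (!inherits(calls, "rhythm_calls")) stop("'calls' must come from classify_rhythms()")
  cyc <- calls[calls$is_cyclic, , drop = FALSE]
  unassigned <- "Unassigned and hypothetical"
  if (is.null(categories)) {
    cat_of <- rep(unassigned, nrow(cyc))
  } else {
    if (anyDuplicated(categories$gene)) stop("a gene may carry at most one category")
    cat_of <- categories$category[match(cyc$gene, categories$gene)]
    cat_of[is.na(cat_of)] <- unassigned
  }
  cats <- sort(unique(c(cat_of, if (nrow(cyc) == 0) character(0))))
  tab <- table(factor(cat_of, levels = cats),
               factor(cyc$peak_label, levels = grid$label_levels))
  matrix(as.integer(tab), nrow = length(cats), ncol = length(grid$label_levels),
         dimnames = list(cats, grid$label_levels))
}
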