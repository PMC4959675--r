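# Independent oracles used to cross-check the package implementations.
# They are written in a deliberately different style (explicit loops, the
# polar model form, union-find, vertex enumeration) so agreement is
# evidence, not tautology.

# Exhaustive cosine-period scan: per period, Fourier sums and the residual
# of the polar-form model R*cos(2*pi*t/T - phi), minimum Ef wins (first on
# ties).
naive_best_fit <- function(gp, t, periods) {
  best <- NULL
  for (T in periods) {
    a <- 0; b <- 0
    for (i in seq_along(t)) {
      a <- a + gp[i] * cos(2 * pi * t[i] / T)
      b <- b + gp[i] * sin(2 * pi * t[i] / T)
    }
    a <- 2 * a / length(t); b <- 2 * b / length(t)
    phi <- atan2(b, a)
    Fi <- sqrt(a^2 + b^2) * cos(2 * pi * t / T - phi)
    ef <- sum((gp - Fi)^2) / length(t)
    if (is.null(best) || ef < best$ef - 1e-15) best <- list(period = T, ef = ef, a = a, b = b)
  }
  best
}

# Hand-executed Holm step-down: sort, cumulative max of (m - k + 1) * p,
# capped at 1.
naive_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Union-find connected components over a thresholded correlation matrix.
uf_components <- function(r, threshold) {
  n <- nrow(r)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(r), roots)
}

# Vertex enumeration for max obj'v s.t. S v = 0, lb <= v <= ub: fix
# n - rank(S) variables at a bound, solve for the rest, keep feasible
# points, return the best objective. Exact for non-degenerate polytopes of
# the sizes used in tests.
vertex_fba_oracle <- function(S, lb, ub, obj) {
  n <- ncol(S)
  k <- n - qr(S)$rank
  best <- -Inf
  subsets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (fix in subsets) {
    free <- setdiff(seq_len(n), fix)
    Sf <- S[, free, drop = FALSE]
    if (length(free) && qr(Sf)$rank < length(free)) next
    n_assign <- 2^length(fix)
    for (mask in seq_len(n_assign) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_along(fix) - 1L)) > 0)
      vf <- ifelse(at_ub, ub[fix], lb[fix])
      v <- numeric(n)
      v[fix] <- vf
      if (length(free)) {
        rhs <- -S[, fix, drop = FALSE] %*% matrix(vf, ncol = 1)
        sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
      }
      if (max(abs(S %*% v)) > 1e-8) next
      if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# Effective bounds of solve_fba for a given phase (re-derived here so the
# oracle does not call into the solver path).
phase_bounds <- function(model, phase, activities = NULL) {
  rx <- model$reactions
  a <- stats::setNames(rep(1, nrow(rx)), rx$id)
  if (!is.null(activities)) a[names(activities)] <- activities
  lb <- a * rx$lb; ub <- a * rx$ub
  caps <- model$nutrient_caps[[phase]]
  k <- match(names(caps), rx$id)
  ub[k] <- pmin(ub[k], caps); lb[k] <- pmin(lb[k], ub[k])
  other <- if (phase == "light") model$biomass$dark else model$biomass$light
  ko <- match(other, rx$id)
  lb[ko] <- 0; ub[ko] <- 0
  list(lb = unname(lb), ub = unname(ub),
       obj = as.numeric(rx$id == model$biomass[[phase]]))
}

# Minimal linear chain model: EX_A (capped) -> A, R1 (gene g1): A -> B,
# BIO_L / BIO_D drain B. Used for proportional-bound and oracle checks.
chain_model <- function(cap = 10) {
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"),
                                       c("EX_A", "R1", "BIO_L", "BIO_D")))
  S["A", "EX_A"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "BIO_L"] <- -1
  S["B", "BIO_D"] <- -1
  metabolic_model(
    id = "chain",
    S = S,
    reactions = data.frame(id = colnames(S),
                           lb = c(0, 0, 0, 0), ub = c(cap, cap, 1000, 1000),
                           gpr = c("", "g1", "", ""),
                           pathway = c("Transport", "Core", "Biomass", "Biomass"),
                           stringsAsFactors = FALSE),
    biomass = list(light = "BIO_L", dark = "BIO_D"),
    nutrient_caps = list(light = c(EX_A = cap), dark = c(EX_A = cap))
  )
}

# Fabricated rhythm-call table for stages that only need gene, is_cyclic
# and peak_label.
fake_calls <- function(genes, cyclic = rep(TRUE, length(genes)),
                       peak_label = rep("L1", length(genes))) {
  calls <- data.frame(gene = genes, is_cyclic = cyclic,
                      peak_label = peak_label, stringsAsFactors = FALSE)
  class(calls) <- c("rhythm_calls", "data.frame")
  calls
}

# Two anti-phase synthetic clusters on the canonical grid; peaks at t = 15 h
# (label L3, light) and t = 3 h (label D3, dark).
antiphase_matrix <- function(n_light = 20, n_dark = 15, noise = 1e-3, seed = 42) {
  set.seed(seed)
  g <- diel_grid()
  rows <- rbind(
    t(replicate(n_light, cos(2 * pi * (g$time - 15) / 24) + rnorm(24, 0, noise))),
    t(replicate(n_dark, cos(2 * pi * (g$time - 3) / 24) + rnorm(24, 0, noise)))
  )
  rownames(rows) <- sprintf("s%03d", seq_len(nrow(rows)))
  colnames(rows) <- paste0(g$label, "_", g$cycle)
  attr(rows, "scaled") <- FALSE
  attr(rows, "grid") <- g
  rows
}
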