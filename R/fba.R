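#' Reactions carrying at least one cyclic gene
#'
#' A reaction is diurnally regulated ("cyclic") when any gene of its GPR
#' rule was called cyclic; reactions without genes are never cyclic. Genes
#' absent from the calls table are treated as non-cyclic.
#'
#' @param model A `"metabolic_model"`.
#' @param calls A `"rhythm_calls"` data frame.
#' @return Character vector of cyclic reaction ids.
#' @export
cyclic_reactions <- function(model, calls) {
  if (!inherits(calls, "rhythm_calls")) stop("'calls' must come from classify_rhythms()")
  cyc <- calls$gene[calls$is_cyclic]
  keep <- vapply(model$gpr_trees,
                 function(tr) length(intersect(gpr_genes(tr), cyc)) > 0,
                 logical(1))
  model$reactions$id[keep]
}

#' Diel activity profile of the cyclic genes
#'
#' For each cyclic gene: average the two cycles' values per label (12
#' points), then min-max scale the 12-point series to [0, 1]. The result
#' drives reaction-level flux-bound scaling. A constant series (which a
#' feature-scaled cyclic gene cannot produce) degenerates to all zeros.
#'
#' @param mat Feature-scaled gene x 24 matrix.
#' @param calls A `"rhythm_calls"` data frame.
#' @param grid The [diel_grid()].
#' @return Matrix of class `"activity_profile"`: cyclic genes x 12 labels,
#'   values in [0, 1].
#' @export
activity_profile <- function(mat, calls, grid = diel_grid()) {
  if (!inherits(calls, "rhythm_calls")) stop("'calls' must come from classify_rhythms()")
  .check_canonical_grid(grid)
  cyc <- intersect(calls$gene[calls$is_cyclic], rownames(mat))
  prof <- t(vapply(cyc, function(g) .cycle_average(mat[g, ], grid),
                   numeric(length(grid$label_levels))))
  if (length(cyc) == 0)
    prof <- matrix(numeric(0), 0, length(grid$label_levels),
                   dimnames = list(NULL, grid$label_levels))
  rng <- apply(prof, 1, max) - apply(prof, 1, min)
  mins <- apply(prof, 1, min)
  scaled <- prof
  ok <- rng > 0
  scaled[ok, ] <- (prof[ok, , drop = FALSE] - mins[ok]) / rng[ok]
  scaled[!ok, ] <- 0
  class(scaled) <- c("activity_profile", class(scaled))
  scaled
}

# Evaluate a GPR tree over the cyclic-gene values available at one label.
# Non-cyclic genes are absent from `values` and are ignored (NA): a complex
# takes the min of its cyclic subunits, isozymes the sum of their cyclic
# members. Returns NA when the subtree contains no cyclic gene.
.eval_gpr_activity <- function(tree, values) {
  if (tree$op == "gene") {
    if (tree$gene %in% names(values)) return(unname(values[tree$gene]))
    return(NA_real_)
  }
  child <- vapply(tree$children, .eval_gpr_activity, numeric(1), values = values)
  child <- child[!is.na(child)]
  if (!length(child)) return(NA_real_)
  if (tree$op == "and") min(child) else sum(child)
}

#' Expression-derived flux-bound scaling factors
#'
#' For one timepoint label, computes the multiplier a_j applied to each
#' reaction's flux bounds: for a cyclic reaction the GPR tree is evaluated
#' over the activity values of its cyclic genes (minimum across complex
#' subunits, sum across isozymes, recursively for nested rules); every
#' non-cyclic reaction gets a_j = 1. Isozyme sums may exceed 1, widening
#' bounds beyond the model's nominal maximum; set `cap = TRUE` to clamp
#' a_j at 1.
#'
#' @param model A `"metabolic_model"`.
#' @param profile An [activity_profile()].
#' @param label One of the 12 timepoint labels.
#' @param cap Clamp a_j at 1?
#' @return Named numeric vector over all model reactions.
#' @export
reaction_activity <- function(model, profile, label, cap = FALSE) {
  if (!label %in% colnames(profile))
    stop("unknown label '", label, "'")
  values <- profile[, label]
  names(values) <- rownames(profile)
  a <- vapply(seq_along(model$gpr_trees), function(k) {
    tr <- model$gpr_trees[[k]]
    if (is.null(tr)) return(1)
    v <- .eval_gpr_activity(tr, values)
    if (is.na(v)) 1 else v          # no cyclic gene involved -> unregulated
  }, numeric(1))
  if (cap) a <- pmin(a, 1)
  stats::setNames(a, model$reactions$id)
}

# --- dense two-phase simplex -------------------------------------------------
# min c'x s.t. A x = b, x >= 0 (b may have any sign; rows are flipped).
# Bland's rule on both the entering and the leaving choice guarantees
# termination without cycling; reduced costs are recomputed from the current
# tableau every iteration, which is cheap at the problem sizes a curated
# metabolic model produces and avoids drift in the objective row.
.simplex_phase <- function(Tb, rhs, basis, cost, tol = 1e-9) {
  M <- nrow(Tb)
  repeat {
    cb <- cost[basis]
    red <- cost - as.vector(cb %*% Tb)
    red[basis] <- 0
    enter <- which(red < -tol)
    if (!length(enter)) return(list(Tb = Tb, rhs = rhs, basis = basis, status = "optimal"))
    e <- min(enter)                                  # Bland: smallest index
    col <- Tb[, e]
    rows <- which(col > tol)
    if (!length(rows)) return(list(Tb = Tb, rhs = rhs, basis = basis, status = "unbounded"))
    ratio <- rhs[rows] / col[rows]
    cand <- rows[ratio <= min(ratio) + tol]
    l <- cand[which.min(basis[cand])]                # Bland tie-break
    piv <- Tb[l, e]
    Tb[l, ] <- Tb[l, ] / piv
    rhs[l] <- rhs[l] / piv
    other <- setdiff(seq_len(M), l)
    rhs[other] <- rhs[other] - Tb[other, e] * rhs[l]
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, e], Tb[l, ])
    Tb[, e] <- 0; Tb[l, e] <- 1                      # keep the unit column exact
    basis[l] <- e
  }
}

# min c'x, A x = b, x >= 0. Returns status, x, objective.
.lp_standard <- function(A, b, cost, tol = 1e-9) {
  M <- nrow(A); N <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1: artificial basis
  Tb <- cbind(A, diag(M))
  basis <- N + seq_len(M)
  p1 <- .simplex_phase(Tb, b, basis, c(rep(0, N), rep(1, M)), tol)
  art_val <- sum(p1$rhs[p1$basis > N])
  if (p1$status != "optimal" || art_val > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  Tb <- p1$Tb; rhs <- p1$rhs; basis <- p1$basis
  # drive residual zero-level artificials out; a row with no structural
  # pivot is redundant and dropped
  drop_rows <- integer(0)
  for (i in which(basis > N)) {
    j <- which(abs(Tb[i, seq_len(N)]) > tol)
    if (!length(j)) { drop_rows <- c(drop_rows, i); next }
    j <- j[1]
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv; rhs[i] <- rhs[i] / piv
    other <- setdiff(seq_len(nrow(Tb)), i)
    rhs[other] <- rhs[other] - Tb[other, j] * rhs[i]
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
    Tb[, j] <- 0; Tb[i, j] <- 1
    basis[i] <- j
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    rhs <- rhs[-drop_rows]
    basis <- basis[-drop_rows]
  }
  # phase 2 on the structural columns only
  p2 <- .simplex_phase(Tb[, seq_len(N), drop = FALSE], rhs, basis, cost, tol)
  if (p2$status != "optimal")
    return(list(status = p2$status, x = NULL, objective = NA_real_))
  x <- rep(0, N)
  x[p2$basis] <- p2$rhs
  list(status = "optimal", x = x, objective = sum(cost * x))
}

# Solve max/min obj'v s.t. S v = 0, lb <= v <= ub (+ optional equality rows
# E v = f). Reactions fixed at zero are dropped; an irreversible reaction
# maps to one non-negative variable (sign-flipped when ub <= 0); reactions
# with lb < 0 < ub are split into positive and negative parts. With
# abs_objective = TRUE the minimized objective is sum(|v|) (unit cost on
# every column), used for the parsimonious secondary solve.
.solve_lp <- function(obj, S, lb, ub, maximize = TRUE, E = NULL, f = NULL,
                      abs_objective = FALSE) {
  m <- length(obj)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("LP requires finite bounds on every reaction")
  Aeq <- rbind(S, E)
  beq <- c(rep(0, nrow(S)), f)

  idx <- integer(0); sgn <- numeric(0)   # reaction and sign of each column
  for (j in seq_len(m)) {
    if (lb[j] == 0 && ub[j] == 0) next
    if (lb[j] >= 0) { idx <- c(idx, j); sgn <- c(sgn, 1) }
    else if (ub[j] <= 0) { idx <- c(idx, j); sgn <- c(sgn, -1) }
    else { idx <- c(idx, j, j); sgn <- c(sgn, 1, -1) }
  }
  if (!length(idx)) {
    feas <- all(abs(beq) <= 1e-9)
    return(list(status = if (feas) "optimal" else "infeasible",
                objective = if (feas) 0 else NA_real_, v = rep(0, m)))
  }
  nx <- length(idx)
  Ax <- Aeq[, idx, drop = FALSE] * rep(sgn, each = nrow(Aeq))
  ax <- if (abs_objective) rep(1, nx) else obj[idx] * sgn
  cap <- ifelse(sgn > 0, ub[idx], -lb[idx])          # > 0 by construction
  low <- ifelse(sgn > 0, pmax(lb[idx], 0), pmax(-ub[idx], 0))

  # standard form: [Ax 0 0; I I 0; I_pos 0 -I] (cap slacks, lower surpluses)
  pos <- which(low > 0)
  n_slack <- nx; n_sur <- length(pos)
  A <- rbind(
    cbind(Ax, matrix(0, nrow(Ax), n_slack + n_sur)),
    cbind(diag(nx), diag(n_slack), matrix(0, nx, n_sur)),
    if (n_sur) cbind(diag(nx)[pos, , drop = FALSE], matrix(0, n_sur, n_slack),
                     -diag(n_sur))
  )
  b <- c(beq, cap, low[pos])
  cost <- c(if (maximize && !abs_objective) -ax else ax,
            rep(0, n_slack + n_sur))
  res <- .lp_standard(A, b, cost)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, v = rep(NA_real_, m)))
  v <- rep(0, m)
  for (k in seq_len(nx)) v[idx[k]] <- v[idx[k]] + sgn[k] * res$x[k]
  list(status = "optimal", objective = sum(obj * v), v = v)
}

#' Solve expression-constrained flux balance analysis at one timepoint
#'
#' Maximizes the biomass flux of the requested phase subject to
#' steady-state mass balance `S v = 0`, activity-scaled bounds
#' `a_j lb_j <= v_j <= a_j ub_j`, and the phase's nutrient uptake caps
#' (dark: glycogen open, photons and inorganic carbon closed; light:
#' photons and CO2/H2CO3 open, glycogen closed — whatever the model's
#' `nutrient_caps` encode). The other phase's biomass reaction is closed.
#' Among alternate optima the returned flux vector additionally minimizes
#' the total absolute flux at the fixed optimum (a second LP), making
#' pathway profiles deterministic.
#'
#' @param model A `"metabolic_model"`.
#' @param activities Named a_j vector from [reaction_activity()]
#'   (default: all 1, plain FBA).
#' @param phase `"light"` or `"dark"`.
#' @param label Optional timepoint label recorded in the result.
#' @param parsimonious Run the secondary minimum-|v| LP? (default TRUE)
#' @return Object of class `"flux_solution"`: list with `phase`, `label`,
#'   `status`, `objective` (biomass flux), `fluxes` (named vector),
#'   `activities`.
#' @export
solve_fba <- function(model, activities = NULL, phase = c("light", "dark"),
                      label = NULL, parsimonious = TRUE) {
  phase <- match.arg(phase)
  rx <- model$reactions
  m <- nrow(rx)
  a <- stats::setNames(rep(1, m), rx$id)
  if (!is.null(activities)) {
    unknown <- setdiff(names(activities), rx$id)
    if (length(unknown)) stop("activities for unknown reaction(s): ",
                              paste(unknown, collapse = ", "))
    if (any(activities < 0)) stop("activity factors must be non-negative")
    a[names(activities)] <- activities
  }
  lb <- a * rx$lb
  ub <- a * rx$ub
  caps <- model$nutrient_caps[[phase]]
  if (!is.null(caps)) {
    k <- match(names(caps), rx$id)
    ub[k] <- pmin(ub[k], caps)
    lb[k] <- pmin(lb[k], ub[k])
  }
  other <- if (phase == "light") model$biomass$dark else model$biomass$light
  ko <- match(other, rx$id)
  lb[ko] <- 0; ub[ko] <- 0
  obj <- as.numeric(rx$id == model$biomass[[phase]])

  sol <- .solve_lp(obj, model$S, lb, ub, maximize = TRUE)
  if (sol$status == "infeasible") {
    closed <- rx$id[a == 0]
    stop("FBA infeasible in ", phase, " phase",
         if (length(closed)) paste0("; reactions closed by a_j = 0: ",
                                    paste(closed, collapse = ", ")) else "")
  }
  if (sol$status == "unbounded") stop("FBA unbounded: check model bounds")
  v <- sol$v
  if (parsimonious) {
    sec <- .solve_lp(rep(1, m), model$S, lb, ub, maximize = FALSE,
                     E = matrix(obj, nrow = 1), f = sol$objective,
                     abs_objective = TRUE)
    if (sec$status == "optimal") v <- sec$v
  }
  out <- list(phase = phase, label = label, status = "optimal",
              objective = sol$objective,
              fluxes = stats::setNames(v, rx$id),
              activities = a)
  class(out) <- "flux_solution"
  out
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution (", x$phase, if (!is.null(x$label)) paste0(", ", x$label), "): ",
      "biomass = ", signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}

#' Solve FBA across the 12 diel timepoints
#'
#' Runs [solve_fba()] at every distinct label with that label's
#' expression-derived activity factors; labels starting with "L" use the
#' light phase configuration, "D" the dark one.
#'
#' @param model A `"metabolic_model"`.
#' @param profile An [activity_profile()]; `NULL` gives plain FBA at every
#'   label.
#' @param grid The [diel_grid()].
#' @param cap Passed to [reaction_activity()].
#' @return Named list of `"flux_solution"` objects, one per label in
#'   D1...L11 order.
#' @export
solve_fba_series <- function(model, profile = NULL, grid = diel_grid(),
                             cap = FALSE) {
  sols <- lapply(grid$label_levels, function(lab) {
    act <- if (is.null(profile)) NULL else reaction_activity(model, profile, lab, cap = cap)
    solve_fba(model, act, phase = label_phase(lab), label = lab)
  })
  stats::setNames(sols, grid$label_levels)
}

#' Pathway-averaged, 0-1 scaled diel flux profiles
#'
#' At each timepoint a pathway's value is the mean absolute flux of its
#' member reactions (absolute, so reversible members do not cancel); each
#' pathway's 12-point series is then min-max scaled to [0, 1]. A pathway
#' whose fluxes never change maps to all zeros.
#'
#' @param solutions Named list of 12 `"flux_solution"`s
#'   ([solve_fba_series()]).
#' @param model The model the solutions came from.
#' @param exclude Pathway labels to omit (default the biomass pseudo
#'   pathway, if present).
#' @return Matrix pathways x 12 labels with values in [0, 1].
#' @export
pathway_fluxes <- function(solutions, model, exclude = "Biomass") {
  labs <- names(solutions)
  paths <- setdiff(unique(model$reactions$pathway), exclude)
  raw <- matrix(NA_real_, length(paths), length(labs),
                dimnames = list(paths, labs))
  for (p in paths) {
    members <- model$reactions$id[model$reactions$pathway == p]
    if (!length(members)) { warning("pathway '", p, "' has no reactions; excluded"); next }
    raw[p, ] <- vapply(solutions, function(s) mean(abs(s$fluxes[members])), numeric(1))
  }
  raw <- raw[!apply(raw, 1, anyNA), , drop = FALSE]
  rng <- apply(raw, 1, max) - apply(raw, 1, min)
  mins <- apply(raw, 1, min)
  out <- raw
  ok <- rng > 0
  out[ok, ] <- (raw[ok, , drop = FALSE] - mins[ok]) / rng[ok]
  out[!ok, ] <- 0
  out
}
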