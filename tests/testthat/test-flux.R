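grid <- diel_grid()
toy <- generate_toy_model()

test_that("cyclic reactions are those with at least one cyclic gene", {
  calls <- fake_calls(c("glgP2", "rbcL", "pgi"))   # one isozyme, one subunit, one single
  cyc <- cyclic_reactions(toy, calls)
  expect_setequal(cyc, c("GLG_degrade", "CBB_fix", "GLY_catabolism"))
  # empty GPRs never qualify; no cyclic genes means no cyclic reactions
  expect_false(any(c("EX_photon", "BIOMASS_light") %in% cyc))
  expect_length(cyclic_reactions(toy, fake_calls("nope", cyclic = FALSE)), 0L)
})

test_that("activity factors follow the min/sum/1 rules", {
  prof <- matrix(c(0.2, 0.8, 0.5, 0.5),
                 nrow = 4, ncol = 12,
                 dimnames = list(c("rbcL", "rbcS", "glgP1", "glgP2"),
                                 grid$label_levels))
  a <- reaction_activity(toy, prof, "D1")
  expect_equal(unname(a["CBB_fix"]), 0.2)         # complex: min of subunits
  expect_equal(unname(a["GLG_degrade"]), 1.0)     # isozymes: sum of members
  expect_equal(unname(a["EX_photon"]), 1)         # gene-free: unregulated
  expect_equal(unname(a["RESP_oxphos"]), 1)       # no cyclic gene involved
  # non-cyclic genes inside a rule are ignored, not zeroed
  prof2 <- prof[c("rbcL", "glgP1"), , drop = FALSE]
  a2 <- reaction_activity(toy, prof2, "D1")
  expect_equal(unname(a2["CBB_fix"]), 0.2)        # rbcS absent from the min
  expect_equal(unname(a2["GLG_degrade"]), 0.5)    # glgP2 absent from the sum
  # nested OR of ANDs: min inside each complex, sum across isozymes
  prof3 <- matrix(c(0.3, 0.9, 0.4), nrow = 3, ncol = 12,
                  dimnames = list(c("ndhA", "ndhB", "cox1"), grid$label_levels))
  a3 <- reaction_activity(toy, prof3, "L1")
  expect_equal(unname(a3["RESP_oxphos"]), min(0.3, 0.9) + 0.4)
  # optional cap clamps sums at 1
  prof4 <- matrix(c(0.8, 0.8), nrow = 2, ncol = 12,
                  dimnames = list(c("glgP1", "glgP2"), grid$label_levels))
  expect_equal(unname(reaction_activity(toy, prof4, "L1")["GLG_degrade"]), 1.6)
  expect_equal(unname(reaction_activity(toy, prof4, "L1", cap = TRUE)["GLG_degrade"]), 1)
})

test_that("activity profiles are cycle-averaged and 0-1 scaled", {
  sim <- generate_expression(synthetic_spec(n_genes = 50, seed = 6), grid)
  scaled <- feature_scale(sim$matrix)
  calls <- classify_rhythms(scaled, grid)
  prof <- activity_profile(scaled, calls, grid)
  expect_equal(nrow(prof), sum(calls$is_cyclic))
  expect_true(all(prof >= 0 & prof <= 1))
  expect_equal(unname(apply(prof, 1, min)), rep(0, nrow(prof)))
  expect_equal(unname(apply(prof, 1, max)), rep(1, nrow(prof)))
  # spot-check the averaging for one gene
  gid <- rownames(prof)[1]
  avg <- (scaled[gid, 1:12] + scaled[gid, 13:24]) / 2
  expect_equal(unname(prof[gid, ]),
               unname((avg - min(avg)) / (max(avg) - min(avg))),
               tolerance = 1e-12)
})

test_that("FBA optima agree with exhaustive vertex enumeration", {
  # chain model (rank 2, 4 reactions) and the 12-reaction toy, both phases
  for (model in list(chain_model(), toy)) {
    for (phase in c("light", "dark")) {
      pb <- phase_bounds(model, phase)
      want <- vertex_fba_oracle(model$S, pb$lb, pb$ub, pb$obj)
      got <- solve_fba(model, phase = phase)$objective
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("activity scaling throttles and closes reactions proportionally", {
  ch <- chain_model(cap = 10)
  # a bottleneck R1 bound of 10 scaled by 0.5 halves the optimum
  expect_equal(solve_fba(ch, phase = "light")$objective, 10, tolerance = 1e-9)
  s5 <- solve_fba(ch, c(R1 = 0.5), phase = "light")
  expect_equal(s5$objective, 5, tolerance = 1e-9)
  s0 <- solve_fba(ch, c(R1 = 0), phase = "light")
  expect_equal(s0$objective, 0, tolerance = 1e-12)
  expect_equal(unname(s0$fluxes["R1"]), 0)
})

test_that("optimal biomass is monotone non-decreasing in any single a_j", {
  prev <- -Inf
  for (a in seq(0, 1, by = 0.2)) {
    obj <- solve_fba(toy, c(GLG_degrade = a), phase = "dark")$objective
    expect_gte(obj, prev - 1e-9)
    prev <- obj
  }
  prev <- -Inf
  for (a in seq(0, 1, by = 0.25)) {
    obj <- solve_fba(toy, c(CBB_fix = a * 0.01), phase = "light")$objective
    expect_gte(obj, prev - 1e-9)
    prev <- obj
  }
})

test_that("all activities at 1 reduce to plain FBA", {
  ones <- setNames(rep(1, nrow(toy$reactions)), toy$reactions$id)
  for (phase in c("light", "dark")) {
    expect_equal(solve_fba(toy, ones, phase = phase)$objective,
                 solve_fba(toy, phase = phase)$objective,
                 tolerance = 1e-10)
  }
})

test_that("solutions satisfy mass balance and scaled bounds at every label", {
  sim <- generate_expression(synthetic_spec(n_genes = 60, seed = 14), grid)
  scaled <- feature_scale(sim$matrix)
  calls <- classify_rhythms(scaled, grid)
  prof <- activity_profile(scaled, calls, grid)
  rownames(prof)[seq_along(sort(model_genes(toy)))] <- sort(model_genes(toy))
  sols <- solve_fba_series(toy, prof, grid)
  expect_named(sols, grid$label_levels)
  for (lab in grid$label_levels) {
    s <- sols[[lab]]
    expect_lte(max(abs(toy$S %*% s$fluxes)), 1e-6)
    a <- s$activities
    lb <- a * toy$reactions$lb; ub <- a * toy$reactions$ub
    caps <- toy$nutrient_caps[[s$phase]]
    k <- match(names(caps), toy$reactions$id)
    ub[k] <- pmin(ub[k], caps); lb[k] <- pmin(lb[k], ub[k])
    expect_true(all(s$fluxes >= lb - 1e-9 & s$fluxes <= ub + 1e-9))
  }
})

test_that("pathway profiles average member fluxes and scale to [0, 1]", {
  sols <- lapply(grid$label_levels, function(lab)
    solve_fba(toy, phase = label_phase(lab), label = lab))
  names(sols) <- grid$label_levels
  prof <- pathway_fluxes(sols, toy)
  expect_true(all(prof >= 0 & prof <= 1))
  expect_false("Biomass" %in% rownames(prof))
  # plain FBA per phase is label-invariant within a phase, so every pathway
  # profile is two-valued; check the Calvin-cycle pathway follows raw fluxes
  raw <- vapply(sols, function(s) mean(abs(s$fluxes["CBB_fix"])), numeric(1))
  rng <- range(raw)
  want <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
  expect_equal(unname(prof["Calvin cycle", ]), unname(want), tolerance = 1e-9)
})

test_that("infeasibility from a zero activity is reported with the culprit", {
  ch <- chain_model()
  ch$reactions$lb[ch$reactions$id == "BIO_L"] <- 2   # must produce, but...
  expect_error(solve_fba(ch, c(R1 = 0), phase = "light"), "R1")
})

test_that("model JSON round-trips and SBML FBC import reconstructs the chain", {
  f <- tempfile(fileext = ".json")
  write_model_json(toy, f)
  back <- read_model_json(f)
  expect_equal(back$S, toy$S)
  expect_equal(back$reactions, toy$reactions)
  expect_equal(back$nutrient_caps, toy$nutrient_caps)
  expect_equal(solve_fba(back, phase = "light")$objective,
               solve_fba(toy, phase = "light")$objective)

  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" fbc:required="false">',
    '<model id="chain">',
    '<listOfParameters>',
    '<parameter id="zero" value="0" constant="true"/>',
    '<parameter id="cap" value="10" constant="true"/>',
    '<parameter id="big" value="1000" constant="true"/>',
    '</listOfParameters>',
    '<fbc:listOfGeneProducts xmlns="http://www.sbml.org/sbml/level3/version1/fbc/version2">',
    '<geneProduct id="gp1" label="g1"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfSpecies>',
    '<species id="A"/><species id="B"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="false" lowerFluxBound="zero" upperFluxBound="cap">',
    '  <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R1" reversible="false" lowerFluxBound="zero" upperFluxBound="cap">',
    '  <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '  <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '  <geneProductAssociation><geneProductRef geneProduct="gp1"/></geneProductAssociation>',
    '</reaction>',
    '<reaction id="BIO_L" reversible="false" lowerFluxBound="zero" upperFluxBound="big">',
    '  <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="BIO_D" reversible="false" lowerFluxBound="zero" upperFluxBound="big">',
    '  <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'
  )
  sf <- tempfile(fileext = ".xml")
  writeLines(sbml, sf)
  sm <- read_sbml_model(sf, biomass = list(light = "BIO_L", dark = "BIO_D"),
                        nutrient_caps = list(light = c(EX_A = 10), dark = c(EX_A = 10)))
  expect_equal(sm$reactions$gpr[sm$reactions$id == "R1"], "g1")
  expect_equal(sm$reactions$ub[sm$reactions$id == "EX_A"], 10)
  expect_equal(sm$S["A", "R1"], -1)
  expect_equal(solve_fba(sm, phase = "light")$objective, 10, tolerance = 1e-9)
})
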