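test_that("scenario networks have the documented reaction and parameter counts", {
  h <- build_network("H")
  expect_identical(h$n_reactions, 41L)
  expect_identical(h$n_parameters, 51L)
  a <- build_network("A")
  expect_identical(a$n_reactions, 31L)
  expect_identical(a$n_parameters, 41L)
  for (lab in LETTERS[1:8])
    expect_lte(build_network(lab)$n_parameters, 51L)
})

test_that("disabling a mechanism removes exactly its reactions", {
  a <- build_network("A")
  nm <- function(net) vapply(net$reactions, `[[`, "", "name")
  expect_false(any(grepl("duplex|AR|OAp|Ract", nm(a))))
  # C vs E differ exactly by the AR-complex (RA) reactions
  c_ <- build_network("C"); e_ <- build_network("E")
  added <- setdiff(nm(e_), nm(c_))
  mech <- vapply(e_$reactions[match(added, nm(e_))], `[[`, "", "mechanism")
  expect_true(all(mech == "RA"))
  expect_identical(sort(nm(c_)), sort(intersect(nm(e_), nm(c_))))
})

test_that("initial state is zero except one free copy of each operator", {
  for (lab in c("A", "C", "H")) {
    net <- build_network(lab)
    y0 <- initial_state(net)
    expect_identical(unname(y0["OR_free"]), 1)
    expect_identical(unname(y0["OA_free"]), 1)
    expect_identical(unname(y0["OAp_free"]),
                     if (net$scenario$RA) 1 else 0)
    others <- setdiff(names(y0), c("OR_free", "OA_free", "OAp_free"))
    expect_true(all(y0[others] == 0))
    # operator-state sums at t = 0
    expect_equal(sum(y0[c("OR_free", "OR_1", "OR_2")]), 1)
    expect_equal(sum(y0[c("OA_free", "OA_1", "OA_2")]), 1)
  }
})

test_that("every rate law references only catalogued parameters and species", {
  net <- build_network("H")
  param_ok <- parameter_catalogue()$parameter
  locals_ok <- c(species_table()$species, "esc_r", "esc_a", "R2_nM", "C_mol",
                 "Ce_mol", "OR_tot", "OA_tot", "f_R_fire", "f_A_fire",
                 "as_f", "ra_f", "ract_f", "fx_RA", "fx_Ract", "conv")
  for (r in net$reactions) {
    vars <- all.vars(r$rate)
    expect_true(all(vars %in% c(param_ok, locals_ok)), info = r$name)
    expect_true(all(names(r$stoich) %in% species_table()$species),
                info = r$name)
    expect_true(all(r$params %in% param_ok), info = r$name)
  }
})

test_that("rhs conserves operator copies up to the growth terms", {
  # binding/unbinding moves copies between states; replication and dilution
  # cancel exactly, so each operator total has derivative zero
  for (seed in 1:10) {
    y <- random_state(seed)
    p <- random_params(seed)
    d <- scb_rhs(t = 600 * seed %% 3000, y, p, fx_gp, "H")
    expect_equal(sum(d[c("OR_free", "OR_1", "OR_2")]), 0, tolerance = 1e-12)
    expect_equal(sum(d[c("OA_free", "OA_1", "OA_2")]), 0, tolerance = 1e-12)
    expect_equal(sum(d[c("OAp_free", "OAp_AR")]), 0, tolerance = 1e-12)
  }
})

test_that("rhs agrees with a hand-coded closed form on the repressor-only sub-network", {
  # reduced network: r, R, R2 and the O_R states only (scenario A, all other
  # species zero); the oracle below is written out independently from the
  # mass-action scheme
  for (seed in 1:100) {
    set.seed(seed)
    p <- random_params(seed)
    t <- stats::runif(1, 0, 3600)
    y <- stats::setNames(numeric(18), species_names)
    y["r"] <- stats::runif(1, 0, 50)
    y["R"] <- stats::runif(1, 0, 100)
    y["R2"] <- stats::runif(1, 0, 100)
    w <- stats::runif(3); w <- w / sum(w)
    y[c("OR_free", "OR_1", "OR_2")] <- w

    d <- scb_rhs(t, y, p, fx_gp, "A")

    mu <- baranyi_population(t, fx_gp)$mu
    conv <- 1e9 / (6.02214076e23 * p[["V_cell"]])
    R2n <- conv * y[["R2"]]
    k_FR <- p[["chi"]] * p[["k_FA"]]
    tx <- (k_FR + p[["k_leak_r"]]) * y[["OR_free"]] +
      (k_FR * p[["f_rep1_R"]] + p[["k_leak_r"]]) * y[["OR_1"]] +
      (k_FR * p[["f_rep2_R"]] + p[["k_leak_r"]]) * y[["OR_2"]]
    b1 <- p[["k_on1"]] * R2n * y[["OR_free"]] -
      p[["k_on1"]] * p[["K_d1"]] * y[["OR_1"]]
    b2 <- p[["k_on7"]] * R2n * y[["OR_1"]] -
      p[["k_on7"]] * p[["K_d7"]] * y[["OR_2"]]
    oracle <- c(
      r  = tx - p[["d_r"]] * y[["r"]] - mu * y[["r"]],
      R  = p[["k_TL_r"]] * y[["r"]] - 2 * p[["k_dim"]] * y[["R"]]^2 +
        2 * p[["k_undim"]] * y[["R2"]] - p[["d_R"]] * y[["R"]] -
        mu * y[["R"]],
      R2 = p[["k_dim"]] * y[["R"]]^2 - p[["k_undim"]] * y[["R2"]] -
        p[["d_R2"]] * y[["R2"]] - b1 - b2 - mu * y[["R2"]],
      OR_free = -b1, OR_1 = b1 - b2, OR_2 = b2
    )
    got <- d[names(oracle)]
    scale <- pmax(abs(oracle), 1e-6)
    expect_lt(max(abs(got - oracle) / scale), 1e-10)
  }
})

test_that("structural zeros: disabled-mechanism species never appear", {
  p <- random_params(42)
  sim <- simulate_member(p, "A", fx_gp, times = fx_times)
  expect_sim_ok(sim)
  expect_true(all(sim$trajectory[, c("ra", "AR", "OAp_AR", "OAp_free")] == 0))
})

test_that("scenario nesting: added mechanisms with neutral parameters change nothing", {
  shared <- setdiff(species_names, c("OAp_free", "OAp_AR"))
  for (seed in 1:5) {
    p <- unclass(random_params(seed))
    p[c("k_as", "k_as_off", "d_ra")] <- 0
    p["k_AR_on"] <- 0
    p[c("f_Ract", "f_RA")] <- 1
    p <- parameter_set(p)
    base <- simulate_member(p, "A", fx_gp, times = fx_times)
    expect_sim_ok(base)
    for (lab in c("C", "D", "B")) {
      alt <- simulate_member(p, lab, fx_gp, times = fx_times)
      expect_sim_ok(alt)
      expect_lt(max(abs(alt$trajectory[, shared] -
                          base$trajectory[, shared])), 1e-8)
    }
  }
})

test_that("rhs special cases behave", {
  p <- unclass(fx_median_params)
  # no GBL synthesis: C and Ce have no source
  p0 <- p; p0["k_C"] <- 0
  sim <- simulate_member(parameter_set(p0), "C", fx_gp, times = fx_times)
  expect_sim_ok(sim)
  expect_true(all(sim$trajectory[, c("C", "Ce")] == 0))

  # stationary phase (mu = 0): decay of a non-produced species is pure
  # first-order degradation (ScbA with no mRNA has no other source or sink)
  y <- stats::setNames(numeric(18), species_names)
  y["A"] <- 10
  y[c("OR_free", "OA_free")] <- 1
  d <- scb_rhs(1e7, y, fx_median_params, fx_gp, "A")
  expect_equal(unname(d["A"]),
               -unname(fx_median_params["d_A"]) * 10, tolerance = 1e-9)

  # negative state components are rejected at the contract surface
  y_bad <- y; y_bad["r"] <- -1
  expect_error(scb_rhs(0, y_bad, fx_median_params, fx_gp, "A"),
               "negative state")
})

test_that("network JSON dump is complete and valid", {
  net <- build_network("C")
  js <- network_to_json(net)
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(obj$scenario, "C")
  expect_length(obj$reactions, 34)
  expect_true(obj$mechanisms$AS)
  expect_false(obj$mechanisms$RA)
  path <- tempfile(fileext = ".json")
  network_to_json(net, path)
  expect_true(file.exists(path))
})
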