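test_that("grid adjacency has the forced lattice structure", {
  g4 <- gen_adjacency(4, "grid")
  expect_length(g4$nodes, 4)
  expect_true(all(graph_degree(g4) == 2))  # 2x2: every corner has degree 2

  g9 <- gen_adjacency(9, "grid")
  deg <- graph_degree(g9)
  expect_identical(sum(deg == 4), 1L)  # the centre of the 3x3 lattice
  expect_identical(sum(deg == 2), 4L)  # corners
  expect_error(gen_adjacency(1, "grid"), "at least 2")
})

test_that("random planar graphs are seeded, connected and planar-sized", {
  g1 <- gen_adjacency(50, "random-planar", seed = 1)
  g2 <- gen_adjacency(50, "random-planar", seed = 1)
  expect_identical(g1$edges, g2$edges)
  g3 <- gen_adjacency(50, "random-planar", seed = 2)
  expect_false(identical(g1$edges, g3$edges))
  expect_identical(max(graph_components(g1)), 1L)       # Gabriel graphs connect
  expect_lte(nrow(g1$edges), 3 * 50 - 6)                # planarity bound
})

test_that("structured effects are ICAR draws: zero-sum per component", {
  g <- adjacency_graph(sprintf("A%02d", 1:7),
                       rbind(c("A01", "A02"), c("A02", "A03"),
                             c("A04", "A05"), c("A05", "A06"), c("A04", "A06")))
  # components: {1,2,3}, {4,5,6}, island {7}
  truth <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
                     seed = 5)
  comp <- graph_components(g)
  for (c in 1:2) expect_lt(abs(mean(truth$eta[comp == c])), 1e-10)
  expect_identical(unname(truth$eta[7]), 0)  # island convention

  same <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
                    seed = 5)
  expect_identical(truth$eta, same$eta)
  expect_identical(truth$nu, same$nu)

  expect_error(gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 0, rho = 0.5)),
               "sigma")
  expect_error(gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 1.2)),
               "rho")
})

test_that("unstructured effects are standard normal at scale", {
  g <- pair_graph(5000)  # 10,000 areas in 2-node components
  truth <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
                     seed = 11)
  expect_equal(stats::var(truth$nu), 1, tolerance = 0.05)
  expect_lt(abs(mean(truth$nu)), 0.05)
})

test_that("ICAR draws match the pseudo-inverse covariance on a path graph", {
  g <- path_graph(5)
  st <- build_icar_structure(g)
  draws <- t(vapply(1:1500, function(r) {
    gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
              seed = r)$eta
  }, numeric(5)))
  target <- MASS::ginv(unname(as.matrix(st$precision)))
  expect_lt(max(abs(unname(stats::cov(draws)) - target)), 0.12)
})

test_that("area-year counts follow the Poisson generative law", {
  g <- gen_adjacency(100, "grid")
  # all parameters (effectively) zero, population 1000: E = 1, theta = 1
  truth <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1e-8, rho = 0.5),
                     seed = 3)
  frame <- gen_area_year_counts(truth, g, 1:100 + 1919, 1000, seed = 4)
  expect_identical(nrow(frame), 10000L)
  expect_true(all(frame$E == 1))
  expect_equal(mean(frame$Y), 1, tolerance = 0.03)

  # beta0 = log(250): closed-form mean count E * exp(beta0) = 250
  truth2 <- gen_truth(g, list(beta0 = log(250), beta3 = 0, sigma = 1e-8,
                              rho = 0.5), seed = 3)
  frame2 <- gen_area_year_counts(truth2, g, 1:100 + 1919, 1000, seed = 5)
  expect_equal(mean(frame2$Y), 250, tolerance = 0.02 * 250)

  # doubling the population doubles E and the expected counts
  frame4 <- gen_area_year_counts(truth2, g, 1:100 + 1919, 2000, seed = 6)
  expect_true(all(frame4$E == 2 * frame2$E))
  expect_equal(mean(frame4$Y) / mean(frame2$Y), 2, tolerance = 0.05)

  expect_error(gen_area_year_counts(truth, g, 2014, 0), "positive")
})

test_that("time is indexed from the 2019 reference year", {
  g <- gen_adjacency(4, "grid")
  truth <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
                     seed = 1)
  frame <- gen_area_year_counts(truth, g, 2014:2019, 1000, seed = 1)
  expect_setequal(unique(frame$TIME), -5:0)
  expect_identical(frame$TIME, frame$YEAR - 2019L)
})

test_that("disaggregated prescribing rows conserve every area-year count", {
  g <- gen_adjacency(12, "grid")
  truth <- gen_truth(g, list(beta0 = log(5), beta3 = 0.05, sigma = 0.5,
                             rho = 0.7), seed = 21)
  ay <- gen_area_year_counts(truth, g, 2017:2019, 40000, seed = 22)
  drug <- lookup_identifier("0208020AA")  # Edoxaban, strengths 30/60
  files <- gen_prescribing(ay, drug, practices_per_area = 3, seed = 23)

  expect_true(all(files$prescribing$BNF_CODE == "0208020AA"))
  expect_true(all(files$prescribing$QUANTITY == round(files$prescribing$QUANTITY)))
  expect_true(all(files$prescribing$QUANTITY > 0))

  frame <- aggregate_to_area_year(files$prescribing, files$mapping,
                                  files$demography, NULL, drug, 2017:2019)
  key <- paste(frame$AREA_ID, frame$YEAR)
  ay_key <- paste(ay$AREA_ID, ay$YEAR)
  expect_identical(frame$Y, ay$Y[match(key, ay_key)])

  again <- gen_prescribing(ay, drug, practices_per_area = 3, seed = 23)
  expect_identical(files$prescribing, again$prescribing)
})

test_that("single practice, single strength reduces to the DDD identity", {
  g <- gen_adjacency(4, "grid")
  truth <- gen_truth(g, list(beta0 = log(3), beta3 = 0, sigma = 0.3,
                             rho = 0.5), seed = 31)
  ay <- gen_area_year_counts(truth, g, 2019, 20000, seed = 32)
  drug <- drug_identifier("SynthOne", "X00XX00", "000000000",
                          ddd_mg = 10, strengths_mg = 4)
  files <- gen_prescribing(ay, drug, practices_per_area = 1, seed = 33)
  qty <- stats::aggregate(QUANTITY ~ PRACTICE, files$prescribing, sum)
  qty$AREA_ID <- files$mapping$AREA_ID[match(qty$PRACTICE,
                                             files$mapping$PRACTICE)]
  ideal <- ay$Y * drug$ddd_mg / drug$strengths_mg
  got <- qty$QUANTITY[match(ay$AREA_ID, qty$AREA_ID)]
  expect_true(all(abs(got - ideal) <= 1))
})

test_that("the quarterly demography series carries the mid-year population", {
  g <- gen_adjacency(4, "grid")
  truth <- gen_truth(g, list(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5),
                     seed = 41)
  ay <- gen_area_year_counts(truth, g, 2018:2019, 12345, seed = 42)
  files <- gen_prescribing(ay, lookup_identifier("B01AF02"), 2, seed = 43)
  demo <- files$demography
  expect_setequal(unique(substr(demo$PERIOD, 5, 6)), c("01", "04", "07", "10"))
  july <- demo[substr(demo$PERIOD, 5, 6) == "07", ]
  key <- paste(july$AREA_ID, substr(july$PERIOD, 1, 4))
  expect_equal(july$POPULATION,
               ay$POPULATION[match(key, paste(ay$AREA_ID, ay$YEAR))])
})
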