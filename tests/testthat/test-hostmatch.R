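toy_eggs <- function() {
  data.frame(
    egg_id = sprintf("e%02d", 1:9),
    species = c("cuckoo", "cuckoo", "warbler", "warbler", "pipit",
                "pipit", "finch", "finch", "finch"),
    parasitic = c(TRUE, TRUE, rep(FALSE, 7)),
    hosts = c("warbler", "warbler", rep(NA, 7)),
    Sa = c(1500, 1600, 900, 1100, 800, 1200, 2000, 2100, 2200),
    stringsAsFactors = FALSE)
}
toy_map <- function() data.frame(parasite = "cuckoo", host = "warbler")

test_that("host reference value follows the species-mean and multi-host rules", {
  eggs <- toy_eggs()
  expect_equal(
    host_reference_value("cuckoo", eggs, toy_map(), "Sa",
                         rule = "species_mean"), 1000)
  # three candidate hosts -> mean of the three species means
  map3 <- data.frame(parasite = "cuckoo",
                     host = c("warbler", "pipit", "finch"))
  expect_equal(host_reference_value("cuckoo", eggs, map3, "Sa"),
               mean(c(1000, 1000, 2100)))
  # egg sampling draws one of the host's measured eggs
  v <- withr::with_seed(4, host_reference_value("cuckoo", eggs, toy_map(),
                                                "Sa", rule = "egg_sample"))
  expect_true(v %in% c(900, 1100))
  # host with no data: NA with a warning
  eggs$Sa[eggs$species == "warbler"] <- NA
  expect_warning(
    out <- host_reference_value("cuckoo", eggs, toy_map(), "Sa"),
    "no measured")
  expect_true(is.na(out))
})

test_that("pair construction yields one host and one random pair per egg", {
  prs <- build_pairs(toy_eggs(), toy_map(), "Sa", seed = 11)
  expect_equal(attr(prs, "n_host"), 2L)
  expect_equal(attr(prs, "n_random"), 2L)
  expect_true(all(prs$abs_difference >= 0))
  # random partners are never parasitic and never the focal parasite's host
  rnd <- prs[prs$pair_type == "random", ]
  partner_sp <- toy_eggs()$species[match(rnd$partner, toy_eggs()$egg_id)]
  expect_false(any(partner_sp %in% c("warbler", "cuckoo")))

  # reproducible under the seed, variable across seeds
  again <- build_pairs(toy_eggs(), toy_map(), "Sa", seed = 11)
  expect_identical(as.data.frame(prs), as.data.frame(again))

  # empty when no parasitic eggs
  none <- toy_eggs(); none$parasitic <- FALSE; none$hosts <- NA
  expect_warning(empty <- build_pairs(none, toy_map(), "Sa", seed = 1),
                 "no parasitic eggs")
  expect_equal(nrow(empty), 0L)

  # explicit target counts subsample the pairing
  eggsN <- sim_dataset(seed = 5)$eggs
  names(eggsN)[names(eggsN) == "y"] <- "Sa"
  eggsN$Sa <- eggsN$Sa + 100  # keep positive on the standardized scale
  mapN <- unique(eggsN[eggsN$parasitic, c("species", "hosts")])
  mapN <- data.frame(parasite = mapN$species, host = mapN$hosts)
  capped <- build_pairs(eggsN, mapN, "Sa", seed = 2,
                        target_counts = c(host = 20, random = 25))
  expect_equal(attr(capped, "n_host"), 20L)
  expect_equal(attr(capped, "n_random"), 25L)
})

test_that("group comparison reproduces the enumerable toy exactly", {
  toy <- toy_pairs()
  res <- compare_pair_types(toy, n_permutations = 20000, seed = 9)
  expect_equal(res$estimate, 4)
  expect_equal(res$df, 4L)
  expect_equal(res$n_host_pairs, 3L)
  p_exact <- exact_perm_p(toy$abs_difference, 3)
  expect_equal(p_exact, 0.1)
  expect_lt(abs(res$p_permutation - p_exact), 2 / sqrt(20000))

  # identical groups: zero estimate, permutation p ~ 1
  flat <- data.frame(pair_type = rep(c("host", "random"), each = 4),
                     abs_difference = rep(2, 8))
  null <- compare_pair_types(flat, n_permutations = 200, seed = 1)
  expect_equal(null$estimate, 0)
  expect_gt(null$p_permutation, 0.99)
})

test_that("comparison is scale-equivariant and label-symmetric", {
  toy <- toy_pairs()
  res <- compare_pair_types(toy, n_permutations = 2000, seed = 21)
  doubled <- toy; doubled$abs_difference <- 2 * doubled$abs_difference
  res2 <- compare_pair_types(doubled, n_permutations = 2000, seed = 21)
  expect_equal(res2$estimate, 2 * res$estimate)
  expect_equal(res2$t, res$t, tolerance = 1e-12)
  expect_equal(res2$p_parametric, res$p_parametric, tolerance = 1e-12)
  expect_equal(res2$p_permutation, res$p_permutation)

  # swapping which label is called "host" flips the sign only
  flipped <- toy
  flipped$pair_type <- ifelse(toy$pair_type == "host", "random", "host")
  res3 <- compare_pair_types(flipped, n_permutations = 2000, seed = 21)
  expect_equal(res3$estimate, -res$estimate)
  expect_equal(res3$p_permutation, res$p_permutation)

  expect_error(compare_pair_types(toy[toy$pair_type == "host", ]),
               "at least 2 pairs")
})

test_that("permutation test holds its size when pairs are unclustered", {
  # With one egg per species the pair differences carry no within-parasite
  # replication, the exchangeability assumption of the label-shuffling null
  # is (nearly) met, and the test is correctly sized. (With several eggs
  # per parasitic species and strong phylogenetic signal the pairs are
  # clustered and the test is anticonservative; see the methods vignette.)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    ds <- sim_dataset(seed = 600000 + i, eggs_per_species = 1)
    prs <- build_pairs(ds$eggs, ds$hostmap, "y", seed = 700000 + i)
    cmp <- compare_pair_types(prs, n_permutations = 200,
                              seed = 800000 + i)
    cmp$p_permutation <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("host map validation catches self-parasitism and parasitic hosts", {
  expect_error(validate_hostmap(data.frame(parasite = "a", host = "a")),
               "itself")
  eggs <- toy_eggs()
  expect_error(
    validate_hostmap(data.frame(parasite = "finch", host = "cuckoo"), eggs),
    "parasitic in the egg table")
})
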