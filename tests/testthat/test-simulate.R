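test_that("layout places equal quarters on the first section", {
  set.seed(1)
  lay <- layout_domains(400, L = 1)
  expect_equal(lay[[1]]$boundaries, c(1250, 2500, 3750))
  # every cell's domain label agrees with recomputing the band from x
  b <- lay[[1]]$boundaries
  z2 <- findInterval(lay[[1]]$coords[, 1], b) + 1
  expect_equal(lay[[1]]$z, as.integer(z2))
})

test_that("later sections shift boundaries by at most 10% of the width", {
  set.seed(2)
  lay <- layout_domains(100, L = 5, shift_fraction = 0.10, width = 5000)
  for (l in 2:5) {
    d <- lay[[l]]$boundaries - c(1250, 2500, 3750)
    expect_true(all(abs(d) <= 500))
    expect_true(!is.unsorted(lay[[l]]$boundaries, strictly = TRUE))
    z2 <- findInterval(lay[[l]]$coords[, 1], lay[[l]]$boundaries) + 1
    expect_equal(lay[[l]]$z, as.integer(z2))
  }
})

test_that("scenario compositions match the study design", {
  p1 <- spadom:::scenario_pi("I")
  expect_true(all(colSums(p1) == 1))
  expect_true(all(sort(as.numeric(p1)) == rep(c(0, 1), c(12, 4))))
  expect_true(all(colSums(p1 > 0) == 1))  # a permutation matrix

  p2 <- spadom:::scenario_pi("II")
  for (r in 1:4) {
    expect_equal(sort(p2[, r]), c(0, 0.05, 0.05, 0.90))
  }
  p3 <- spadom:::scenario_pi("III")
  for (r in 1:4) expect_equal(sort(p3[, r]), c(0, 0.25, 0.25, 0.50))
  p4 <- spadom:::scenario_pi("IV")
  for (r in 1:4) expect_equal(sort(p4[, r]), c(0, 1 / 3, 1 / 3, 1 / 3))
  # each domain misses a different type in II-IV
  expect_equal(sort(apply(p2, 1, function(x) sum(x == 0))), rep(1, 4))
})

test_that("cells are drawn from their domain's composition", {
  set.seed(3)
  z <- rep(1:4, each = 2500)
  asg <- assign_types(z, "III")
  emp <- table(factor(asg$c, 1:4), factor(z, 1:4)) / 2500
  expect_lt(max(abs(emp - asg$pi)), 0.03)
})

test_that("rare-type designs give the advertised overall fractions", {
  set.seed(4)
  z <- rep(1:4, each = 5000)
  for (n_rare in c(6L, 10L)) {
    for (pat in c("random", "domain_specific")) {
      cfg <- rare_config(n_rare = n_rare, rare_pattern = pat)
      asg <- assign_types_rare(z, cfg)
      expect_equal(colSums(asg$pi), rep(1, 4), tolerance = 1e-12)
      frac <- tabulate(asg$c, 4 + n_rare) / length(z)
      # each rare type near 30% / n_rare of all cells (5% or 3%)
      expect_equal(frac[asg$rare_type_ids],
                   rep(0.3 / n_rare, n_rare), tolerance = 0.25)
      expect_equal(sum(frac[1:4]), 0.7, tolerance = 0.02)
      if (pat == "domain_specific") {
        # every rare-type cell sits in its own domain
        for (t in asg$rare_type_ids) {
          expect_equal(length(unique(z[asg$c == t])), 1L)
        }
      }
    }
  }
  expect_warning(rare_config(n_rare = 5), "study design")
})

test_that("DE factors have the three-fold median at the baseline location", {
  set.seed(5)
  cfg <- sim_config(de_facloc = 1.1, n_genes = 10000, de_prob = 1)
  out <- simulate_counts_splat(rep(1:4, each = 5), cfg)
  up <- out$de_factors[out$de_gene_flags == "up"]
  expect_gt(length(up), 10000)  # 4 types x ~half of 10000 genes
  expect_gt(median(up), 2.7)    # e^1.1, the three-fold change
  expect_lt(median(up), 3.3)
  down <- out$de_factors[out$de_gene_flags == "down"]
  expect_gt(median(1 / down), 2.7)
  expect_lt(median(1 / down), 3.3)
  expect_true(all(out$de_gene_flags %in% c("up", "down", "none")))
  up_frac <- mean(out$de_gene_flags == "up")
  expect_equal(up_frac, 0.5, tolerance = 0.05)  # equal up/down split
})

test_that("without DE all types share one expression profile", {
  set.seed(6)
  cfg <- sim_config(de_prob = 0, n_genes = 100, n_cells_per_section = 400)
  cc <- rep(1:4, each = 100)
  out <- simulate_counts_splat(cc, cfg)
  expect_true(all(out$de_gene_flags == "none"))
  # normalized profiles agree across types (library size cancels)
  prof <- sapply(1:4, function(k) {
    m <- out$counts[, cc == k]
    rowSums(m) / sum(m)
  })
  expect_lt(max(abs(prof - rowMeans(prof))), 0.02)
})

test_that("marginal count means obey the gamma-Poisson hierarchy", {
  set.seed(7)
  cfg <- sim_config(de_prob = 0, n_genes = 50, lib_loc = log(1000),
                    lib_scale = 0.2)
  cc <- rep(1L, 3000)
  out <- simulate_counts_splat(cc, cfg)
  # for a non-DE gene: E[count] = (base_g / sum(base)) * E[library]
  expect_lib <- exp(log(1000) + 0.2^2 / 2)
  expected <- out$base_means / sum(out$base_means) * expect_lib
  obs <- rowMeans(out$counts)
  se <- sqrt(apply(out$counts, 1, var) / 3000)
  expect_gt(mean(abs(obs - expected) < 3 * se + 0.02 * expected), 0.9)
})

test_that("gene exclusion is a seeded uniform subset", {
  set.seed(8)
  m <- matrix(rpois(200 * 10, 3), 200, 10)
  kept <- exclude_genes(m, 50)
  expect_equal(nrow(kept), 50)
  expect_equal(kept, m[attr(kept, "retained"), ], ignore_attr = TRUE)
  expect_identical(exclude_genes(m, 200), m, ignore_attr = TRUE)
  expect_error(exclude_genes(m, 0), "positive")
  expect_error(exclude_genes(m, 300), "exceeds")
})

test_that("the experiment wrapper is deterministic and internally consistent", {
  cfg <- sim_config(scenario = "II", n_cells_per_section = 200, n_genes = 40,
                    n_sections = 2, seed = 9)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$true_c, s2$true_c)
  expect_identical(s1$coords, s2$coords)
  expect_equal(dim(s1$counts), c(40L, 400L))
  expect_equal(length(s1$true_z), 400L)
  expect_equal(colSums(s1$true_pi), rep(1, 4))
  # default geometry matches the study scale
  dflt <- sim_config()
  expect_equal(dflt$n_cells_per_section, 1127)
  expect_equal(dflt$n_genes, 200)
  expect_equal(dflt$de_prob, 0.2)
  expect_equal(dflt$de_facloc, 1.1)
})

test_that("empirical composition converges to the design composition", {
  cfg <- sim_config(scenario = "III", n_cells_per_section = 10000, seed = 10,
                    n_genes = 5)
  set.seed(10)
  lay <- layout_domains(10000, 1)
  asg <- assign_types(lay[[1]]$z, "III")
  tab <- table(factor(asg$c, 1:4), factor(lay[[1]]$z, 1:4))
  emp <- sweep(tab, 2, colSums(tab), "/")
  expect_lt(max(abs(emp - asg$pi)), 0.03)
})

test_that("gene subsetting flows through the experiment wrapper", {
  cfg <- sim_config(n_cells_per_section = 100, n_genes = 80,
                    genes_retained = 30, seed = 11)
  s <- simulate_experiment(cfg)
  expect_equal(nrow(s$counts), 30L)
  expect_equal(length(s$gene_ids), 30L)
  expect_equal(nrow(s$de_gene_flags), 30L)
})
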