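somatic_ids <- function(n) {
  tibble::tibble(id = sprintf("s%d", seq_len(n)))
}

test_that("inclusion probability one puts every variant in all genomes", {
  a <- assign_subclones(somatic_ids(20), n_per_lineage = 5,
                        inclusion_prob = 1, seed = 1)
  expect_identical(nrow(a$membership), 20L * 10L)
  expect_identical(a$n_redrawn, 0L)
})

test_that("subclone assignment is deterministic and re-draws empties", {
  v <- somatic_ids(500)
  a1 <- assign_subclones(v, 5, 0.1, seed = 99)
  a2 <- assign_subclones(v, 5, 0.1, seed = 99)
  expect_identical(a1$membership, a2$membership)
  # every somatic variant belongs to at least one cancer genome
  expect_setequal(unique(a1$membership$id), v$id)
  a3 <- assign_subclones(v, 5, 0.1, seed = 100)
  expect_false(identical(a1$membership, a3$membership))
  # empty input is not an error
  expect_identical(nrow(assign_subclones(somatic_ids(0), 5, 0.5, 1)$membership),
                   0L)
})

test_that("mean memberships match the zero-truncated binomial closed form", {
  n <- 10000
  a <- assign_subclones(somatic_ids(n), 5, 0.5, seed = 7)
  per_variant <- table(a$membership$id)
  m <- 10 * 0.5 / (1 - 0.5^10) # E[Bin(10, .5) | X >= 1]
  ex2 <- (10 * 0.5 * 0.5 + (10 * 0.5)^2) / (1 - 0.5^10)
  se <- sqrt((ex2 - m^2) / n)
  expect_lt(abs(mean(per_variant) - m), 3 * se)
})

test_that("mixture weights are a normalized flat Dirichlet per lineage", {
  m1 <- draw_mixture(1, seed = 3)
  expect_identical(m1$maternal, 1)
  expect_identical(m1$paternal, 1)
  sums <- vapply(1:500, function(s) {
    m <- draw_mixture(5, seed = s)
    c(sum(m$maternal), sum(m$paternal))
  }, numeric(2))
  expect_true(all(abs(sums - 1) < 1e-12))
  # Dirichlet(1) symmetry: each weight has mean 1/5
  w <- t(vapply(1:10000, function(s) draw_mixture(5, seed = s)$maternal,
                numeric(5)))
  se <- sqrt(0.2 * 0.8 / 6 / 10000)
  expect_true(all(abs(colMeans(w) - 0.2) < 4 * se))
})

test_that("a 30% tumor variant reads at 3% under 90% admixture", {
  expect_equal(dilute_af(0.30, 0.9, 0), 0.03)
})

test_that("expected_af matches hand-computed and Monte-Carlo values", {
  v <- make_variants("chr1", 100L, "A", "T", "SNV", origin = "somatic",
                     id = "s1")
  assignment <- structure(list(
    membership = tibble::tibble(id = "s1", lineage = "maternal",
                                genome = 1:2),
    n_per_lineage = 5L, n_redrawn = 0L), class = "subclone_assignment")
  mixture <- structure(list(maternal = c(0.4, 0.3, 0.1, 0.1, 0.1),
                            paternal = rep(0.2, 5)),
                       class = "clone_mixture")
  out <- expected_af(v, assignment, mixture, admixture = 0)
  expect_equal(out$expected_af, 0.35)
  # Monte-Carlo haplotype-draw oracle: draw lineage 1/2 then genome by w
  set.seed(5)
  n <- 2e5
  lin <- sample(c("maternal", "paternal"), n, replace = TRUE)
  gen <- ifelse(lin == "maternal",
                sample.int(5, n, replace = TRUE,
                           prob = mixture$maternal),
                sample.int(5, n, replace = TRUE,
                           prob = mixture$paternal))
  carrier <- lin == "maternal" & gen %in% 1:2
  se <- sqrt(0.35 * 0.65 / n)
  expect_lt(abs(mean(carrier) - out$expected_af), 3 * se)
  # dilution of the same variant
  out9 <- expected_af(v, assignment, mixture, admixture = 0.9)
  expect_equal(out9$expected_af, 0.1 * 0.35)
})

test_that("germline AF is admixture-invariant and somatic AF declines", {
  v <- variant_table(tibble::tibble(
    id = c("g1", "g2", "s1"), contig = "chr1", pos = c(10L, 20L, 30L),
    ref = "A", alt = "T", vclass = "SNV",
    origin = c("germline", "germline", "somatic")))
  v$lineage <- c("maternal", "both", NA)
  assignment <- assign_subclones(v[v$origin == "somatic", ], 5, 0.5, 1)
  mixture <- draw_mixture(5, seed = 2)
  prev <- Inf
  for (a in seq(0, 0.9, by = 0.1)) {
    out <- expected_af(v, assignment, mixture, a)
    expect_equal(out$expected_af[out$id == "g1"], 0.5)
    expect_equal(out$expected_af[out$id == "g2"], 1.0)
    saf <- out$expected_af[out$id == "s1"]
    expect_lt(saf, prev)
    prev <- saf
  }
  # unknown somatic variant is fatal
  v2 <- make_variants("chr1", 40L, "A", "C", "SNV", id = "s99")
  expect_error(expected_af(v2, assignment, mixture, 0), "not in subclone")
})

test_that("expected_af agrees with Monte-Carlo sampling on random setups", {
  set.seed(123)
  n_draw <- 2e5
  for (k in 1:20) {
    v <- make_variants("chr1", 100L, "A", "T", "SNV", id = "s1")
    assignment <- assign_subclones(v, 5, runif(1, 0.1, 0.9),
                                   seed = 1000 + k)
    mixture <- draw_mixture(5, seed = 2000 + k)
    a <- runif(1, 0, 0.9)
    out <- expected_af(v, assignment, mixture, a)
    memb <- assignment$membership
    from_tumor <- runif(n_draw) >= a
    lin <- sample(c("maternal", "paternal"), n_draw, replace = TRUE)
    gen <- ifelse(lin == "maternal",
                  sample.int(5, n_draw, replace = TRUE, prob = mixture$maternal),
                  sample.int(5, n_draw, replace = TRUE, prob = mixture$paternal))
    carrier <- from_tumor &
      paste(lin, gen) %in% paste(memb$lineage, memb$genome)
    p <- out$expected_af
    se <- sqrt(max(p * (1 - p), 1e-9) / n_draw)
    expect_lt(abs(mean(carrier) - p), 4 * se)
  }
})

test_that("the default admixture series has ten tumor samples", {
  m <- draw_mixture(5, seed = 1)
  s <- admixture_series(m)
  expect_identical(nrow(s), 10L)
  expect_equal(s$admixture, seq(0, 0.9, by = 0.1))
  expect_identical(nrow(admixture_series(m, 0.0)), 1L)
  expect_error(admixture_series(m, c(0.1, 0.1)), "duplicate|increasing")
  expect_error(admixture_series(m, c(0.2, 0.1)), "increasing")
  expect_error(admixture_series(m, 0.99), "0.95")
})

test_that("two-genome mixing produces the discrete union truth set", {
  a <- tibble::tibble(contig = "chr1", pos = c(10L, 30L), ref = c("A", "G"),
                      alt = c("T", "C"), gt = c("hom", "het"))
  b <- tibble::tibble(contig = "chr1", pos = c(10L, 20L), ref = c("A", "C"),
                      alt = c("T", "G"), gt = c("hom", "het"))
  mixed <- mix_two_genomes(a, b, ratio = 7 / 8)
  expect_equal(mixed$expected_af[mixed$pos == 20], 7 / 16)
  expect_equal(mixed$expected_af[mixed$pos == 10], 1)
  expect_equal(mixed$expected_af[mixed$pos == 30], (1 / 8) * 0.5)
  half <- mix_two_genomes(a, a, ratio = 0.5)
  expect_equal(half$expected_af[half$pos == 30], 0.5)
  bad <- tibble::tibble(contig = "chr1", pos = 10L, ref = "C", alt = "T",
                        gt = "het")
  expect_error(mix_two_genomes(a, bad, 0.5), "conflicting ref")
})
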