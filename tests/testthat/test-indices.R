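# fixed 4-species distance matrix with the hand-sum values used below
toy_dmat <- function() {
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 4
  d["A", "C"] <- d["C", "A"] <- 5.5
  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 3
  d["B", "D"] <- d["D", "B"] <- 6
  d["C", "D"] <- d["D", "C"] <- 2
  d
}

test_that("TOTPd, AVEPd and MINPd match their hand sums", {
  d <- toy_dmat()
  prof <- c(B = 2L, C = 1L)
  expect_equal(totpd(prof, d, "A"), 2 * 4 + 1 * 5.5)
  expect_equal(avepd(prof, d, "A"), 13.5 / 3)
  expect_equal(minpd(prof, d, "A"), 4)
  # single neighbor: TOTPd = AVEPd = MINPd = that distance
  one <- c(C = 1L)
  expect_equal(totpd(one, d, "A"), 5.5)
  expect_equal(avepd(one, d, "A"), 5.5)
  expect_equal(minpd(one, d, "A"), 5.5)
  # empty profile -> missing
  expect_true(is.na(totpd(integer(0), d, "A")))
  expect_true(is.na(avepd(integer(0), d, "A")))
  expect_true(is.na(minpd(integer(0), d, "A")))
  # unknown species named in the error
  expect_error(totpd(c(Z = 1L), d, "A"), "missing from distance matrix: Z")
})

test_that("raw indices equal the naive loop oracle on random instances", {
  set.seed(11)
  for (rep in 1:50) {
    inst <- random_instance()
    expect_equal(totpd(inst$profile, inst$dmat, inst$focal),
                 unname(oracle_totpd(inst$profile, inst$dmat, inst$focal)))
    expect_equal(avepd(inst$profile, inst$dmat, inst$focal),
                 unname(oracle_avepd(inst$profile, inst$dmat, inst$focal)))
    expect_equal(minpd(inst$profile, inst$dmat, inst$focal),
                 oracle_minpd(inst$profile, inst$dmat, inst$focal))
    # ordering invariant: minpd <= avepd <= totpd (total abundance >= 1)
    expect_lte(minpd(inst$profile, inst$dmat, inst$focal),
               avepd(inst$profile, inst$dmat, inst$focal))
    expect_lte(avepd(inst$profile, inst$dmat, inst$focal),
               totpd(inst$profile, inst$dmat, inst$focal))
  }
})

test_that("SES handles degenerate nulls and bad arguments", {
  # star tree: every pairwise distance 2 -> null SD 0 -> missing SES
  star <- patristic_matrix(read_newick("(A:1,B:1,C:1,D:1);"))
  set.seed(1)
  s <- ses_indices(c(B = 1L), star, "A", n_null = 99)
  expect_true(is.na(s$apd_prime))
  expect_true(is.na(s$ntpd_prime))
  expect_equal(s$null_sd_ave, 0)
  expect_error(ses_indices(c(B = 1L), star, "A", n_null = 1), "n_null")
  # empty profile -> all missing
  s0 <- ses_indices(integer(0), star, "A")
  expect_true(all(is.na(unlist(s0[c("apd_prime", "ntpd_prime")]))))
})

test_that("SES is reproducible, scale-invariant and sign-correct", {
  set.seed(5)
  phy <- ape::rtree(20)
  d <- patristic_matrix(phy)
  prof <- c(stats::setNames(2L, phy$tip.label[3]),
            stats::setNames(1L, phy$tip.label[9]))
  set.seed(99); s1 <- ses_indices(prof, d, phy$tip.label[1], n_null = 499)
  set.seed(99); s2 <- ses_indices(prof, d, phy$tip.label[1], n_null = 499)
  expect_identical(s1, s2)
  # uniform branch-length rescaling cancels in the SES ratio
  set.seed(99); s10 <- ses_indices(prof, d * 10, phy$tip.label[1], n_null = 499)
  expect_equal(s10$apd_prime, s1$apd_prime, tolerance = 1e-10)
  expect_equal(s10$ntpd_prime, s1$ntpd_prime, tolerance = 1e-10)
  expect_equal(s10$null_mean_ave, 10 * s1$null_mean_ave, tolerance = 1e-10)

  # neighbors drawn from the focal's most distant tips -> SES > 0;
  # closest relatives -> SES < 0
  focal <- phy$tip.label[1]
  ord <- names(sort(d[focal, setdiff(phy$tip.label, focal)]))
  far <- stats::setNames(rep(1L, 3), utils::tail(ord, 3))
  near <- stats::setNames(rep(1L, 3), utils::head(ord, 3))
  set.seed(2)
  expect_gt(ses_indices(far, d, focal, n_null = 499)$apd_prime, 0)
  expect_gt(ses_indices(far, d, focal, n_null = 499)$ntpd_prime, 0)
  expect_lt(ses_indices(near, d, focal, n_null = 499)$apd_prime, 0)
  expect_lt(ses_indices(near, d, focal, n_null = 499)$ntpd_prime, 0)
})

test_that("replacing neighbors with more distant species raises all raw indices", {
  set.seed(8)
  phy <- ape::rtree(15)
  d <- patristic_matrix(phy)
  focal <- phy$tip.label[1]
  ord <- names(sort(d[focal, setdiff(phy$tip.label, focal)]))
  near <- stats::setNames(c(2L, 1L), ord[1:2])
  far <- stats::setNames(c(2L, 1L), utils::tail(ord, 2))
  expect_gt(totpd(far, d, focal), totpd(near, d, focal))
  expect_gt(avepd(far, d, focal), avepd(near, d, focal))
  expect_gt(minpd(far, d, focal), minpd(near, d, focal))
})

test_that("index_set and indices_table agree and are seed-stable", {
  p <- toy_plot()
  tree <- read_newick("((alpha:3,beta:3):2,gamma:5);")
  d <- patristic_matrix(tree)
  is1 <- index_set(p, d, "S1", 2020, n_null = 99, seed = 42)
  is2 <- index_set(p, d, "S1", 2020, n_null = 99, seed = 42)
  expect_identical(is1, is2)
  expect_equal(is1$seedling$totpd, d["alpha", "beta"] * 1)

  tab <- indices_table(p, d, years = 2020, n_null = 99, seed = 42)
  expect_equal(sort(unique(tab$layer)), c("adult", "seedling"))
  # one row per (alive focal, layer)
  expect_equal(nrow(tab), 2 * 6)
  tab2 <- indices_table(p, d, years = 2020, n_null = 99, seed = 42)
  expect_identical(tab, tab2)
  # conspecific focals in one quadrat share profiles and null draws
  r1 <- tab[tab$tag == "S1" & tab$layer == "seedling", -1]
  r2 <- tab[tab$tag == "S2" & tab$layer == "seedling", -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
  # empty profiles flagged missing (S5, gamma alone in Q2 seedling layer)
  expect_true(is.na(tab$totpd[tab$tag == "S5" & tab$layer == "seedling"]))
})
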