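test_that("FAM and header dialects parse, with missing parents as 0 or empty", {
  fam <- c("f1 p1 0 0 1 -9",
           "f1 p2 0 0 2 -9",
           "f1 k1 p1 p2 1 -9",
           "f1 k2 p1 p2 2 -9")
  path <- withr::local_tempfile(lines = fam, fileext = ".fam")
  ped <- read_pedigree(path, dialect = "fam")
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 4L)
  expect_equal(sum(is.na(ped$father)), 2L)  # two founders
  expect_setequal(ped$father[ped$id %in% c("k1", "k2")], "p1")

  hdr <- c("fid\tiid\tfather\tmother\tsex",
           "f1\tp1\t\t\t1", "f1\tp2\t0\t0\t2", "f1\tk1\tp1\tp2\t1")
  path2 <- withr::local_tempfile(lines = hdr, fileext = ".ped")
  ped2 <- read_pedigree(path2, dialect = "ped")
  expect_equal(sum(is.na(ped2$father)), 2L)
})

test_that("invalid pedigrees are rejected with the offending id", {
  expect_error(pedigree(id = c("a", "a"), father = NA, mother = NA),
               "duplicate.*a")
  expect_error(
    pedigree(id = c("p", "q", "k"), father = c(NA, NA, "p"),
             mother = c(NA, NA, NA)),
    "one parent.*k")
  expect_error(
    pedigree(id = c("x", "y"), father = c("y", "x"), mother = c("y", "x")),
    "cyclic.*x")
  expect_error(
    pedigree(id = c("p", "q", "k"), father = c(NA, NA, "p"),
             mother = c(NA, NA, "q"), family = c("f1", "f2", "f1")),
    "different family.*k")
  expect_error(
    pedigree(id = c("k"), father = "ghost", mother = "ghost2"),
    "not found.*k")
})

test_that("interleaved families are reordered contiguously, parents first", {
  ped <- pedigree(id = c("a_kid", "b_pa", "a_pa", "b_kid", "a_ma", "b_ma"),
                  father = c("a_pa", NA, NA, "b_pa", NA, NA),
                  mother = c("a_ma", NA, NA, "b_ma", NA, NA),
                  family = c("A", "B", "A", "B", "A", "B"))
  expect_equal(ped$family, c("A", "A", "A", "B", "B", "B"))
  # parents precede children within each family
  expect_equal(ped$id[3], "a_kid")
  expect_equal(ped$id[6], "b_kid")
  expect_setequal(ped$id, c("a_kid", "a_pa", "a_ma", "b_kid", "b_pa", "b_ma"))
})

test_that("family offsets follow the block contract", {
  ped <- pedigree(id = c(paste0("a", 1:7), paste0("b", 1:8)),
                  father = NA, mother = NA,
                  family = rep(c("A", "B"), c(7, 8)))
  off <- family_offsets(ped)
  expect_equal(off$offsets, c(1L, 8L, 16L))
  expect_equal(off$n_fam, 2L)
  expect_equal(off$N, 15L)

  one <- family_offsets(nuclear_ped())
  expect_equal(one$offsets, c(1L, 5L))

  many <- family_offsets(make_pedigree("nuclear", 100))
  expect_equal(many$offsets, seq(1L, 401L, by = 4L))

  bad <- nuclear_ped()
  bad$family <- c("A", "B", "A", "B")  # force non-contiguity
  expect_error(family_offsets(bad), "not contiguous")
})

test_that("kinship gives the standard coefficients and restricts to sampled", {
  ped <- nuclear_ped()
  K <- kinship(ped)
  expect_equal(unname(K["fam1_fa", "fam1_o1"]), 0.25)  # parent-offspring
  expect_equal(unname(K["fam1_o1", "fam1_o2"]), 0.25)  # full sibs
  expect_equal(unname(diag(K)), rep(0.5, 4))
  expect_equal(K, t(K))

  # first cousins through a two-trios structure
  ped2 <- make_pedigree("two_trios", 1)
  K2 <- kinship(ped2)
  expect_equal(unname(K2["F001_t1o01", "F001_t2o01"]), 0.0625)
  # phantom grandparents are excluded from the delivered matrix
  expect_equal(nrow(K2), 6L)
  expect_false(any(grepl("_g", rownames(K2))))

  # projection property: sampling flags only restrict the full matrix
  ped_all <- make_pedigree("two_trios", 1)
  ped_all$sampled <- TRUE
  K_full <- kinship(ped_all)
  expect_equal(K2, K_full[rownames(K2), colnames(K2)])
})

test_that("kinship handles inbreeding and demands sorted input", {
  ped <- pedigree(id = c("f", "m", "s1", "s2", "c"),
                  father = c(NA, NA, "f", "f", "s1"),
                  mother = c(NA, NA, "m", "m", "s2"), family = "x")
  K <- kinship(ped)
  expect_equal(unname(K["c", "c"]), 0.625)  # f = 1/4 from full-sib mating

  unsorted <- ped
  unsorted[] <- ped[c(5, 1:4), ]
  class(unsorted) <- class(ped)
  expect_error(kinship(unsorted), "not topologically sorted")
})

test_that("recursive kinship agrees with gene-dropping Monte Carlo", {
  ped <- pedigree(id = c("f", "m", "s1", "s2", "c"),
                  father = c(NA, NA, "f", "f", "s1"),
                  mother = c(NA, NA, "m", "m", "s2"), family = "x")
  K <- kinship(ped)
  gd <- gene_drop_kinship(ped, n_drop = 2e5, seed = 11)
  se <- sqrt(pmax(K * (1 - K), 0.25 / 4) / gd$n_drop)
  expect_true(all(abs(gd$estimate - K) <= 3 * se + 1e-12))
})

test_that("additive matrix is 2K, PSD and block-diagonal", {
  ped <- make_pedigree("two_trios", 3)
  K <- kinship(ped)
  A <- additive_matrix(K)
  expect_equal(A, 2 * K)
  expect_equal(unname(diag(A)), rep(1, nrow(A)))  # non-inbred
  expect_equal(unname(A[1, 2]), 0.5)              # full sibs
  expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
              >= -1e-8)
  off <- family_offsets(ped)
  expect_equal(sum(abs(A[1:6, 7:18])), 0)  # zero across families
})
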