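test_that("genotype TSV parsing handles values, missing tokens and errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tM1\tM2", "A\t0\t1", "B\t2\tNA", "C\t1\t-9"), f)
  gm <- read_genotype_matrix(f, "tsv")
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(gm$codings["A", "M1"], 0)
  expect_true(is.na(gm$codings["B", "M2"]))   # NA token, not 0
  expect_true(is.na(gm$codings["C", "M2"]))   # -9 token

  # header without a sample-ID label also parses
  writeLines(c("M1\tM2", "A\t0\t1", "B\t2\t0"), f)
  expect_equal(dim(read_genotype_matrix(f, "tsv")), c(2L, 2L))

  # ragged row: error names the offending line
  writeLines(c("sample\tM1\tM2", "A\t0\t1", "B\t2\t0\t1"), f)
  expect_error(read_genotype_matrix(f, "tsv"), "line 3")

  # duplicate marker IDs
  writeLines(c("sample\tM1\tM1", "A\t0\t1", "B\t2\t0"), f)
  expect_error(read_genotype_matrix(f, "tsv"), "duplicate")
})

test_that("plink_raw dialect keeps IID and drops pedigree columns", {
  f <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE M1_A M2_A",
               "F1 ind1 0 0 1 -9 0 2",
               "F2 ind2 0 0 2 -9 1 NA"), f)
  gm <- read_genotype_matrix(f, "plink_raw")
  expect_equal(rownames(gm$codings), c("ind1", "ind2"))
  expect_equal(colnames(gm$codings), c("M1_A", "M2_A"))
  expect_true(is.na(gm$codings["ind2", "M2_A"]))
})

test_that("phenotype reading builds designs and aligns samples", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\theight\tgroup", "S1\t10.5\ta", "S2\t11\tb",
               "S3\t9.8\ta"), f)
  ph <- read_phenotype_table(f, trait = "height")
  expect_equal(length(ph$y), 3L)
  expect_equal(unname(ph$X), matrix(1, 3, 1))

  ph2 <- read_phenotype_table(f, trait = "height", covariates = "group")
  expect_equal(ncol(ph2$X), 2L)   # intercept + one dummy

  writeLines(c("sample\theight", "S1\tten"), f)
  expect_error(read_phenotype_table(f, trait = "height"), "not numeric")

  # alignment to genotypes drops strangers with a warning, errors on no overlap
  gm <- rand_gm(3, 2, 1)
  writeLines(c("sample\theight", "S9\t1", "S2\t2", "S1\t3"), f)
  expect_warning(ph3 <- read_phenotype_table(f, "height", genotypes = gm),
                 "dropped")
  expect_equal(ph3$samples, c("S1", "S2"))
  writeLines(c("sample\theight", "X1\t1", "X2\t2"), f)
  expect_error(suppressWarnings(
    read_phenotype_table(f, "height", genotypes = gm)), "overlap")
})

test_that("imputation fills column means, centres, flags monomorphic, is idempotent", {
  M <- matrix(c(0, 2, NA, 0, 1, 2, 2, 2, 2), 3, 3,
              dimnames = list(paste0("S", 1:3), paste0("M", 1:3)))
  gm <- genotype_matrix(M)
  im <- impute_and_code(gm)
  expect_equal(im$codings["S3", "M1"], 1)        # mean of (0, 2)
  expect_equal(unname(im$monomorphic), c(FALSE, FALSE, TRUE))
  ic <- impute_and_code(gm, center = TRUE)
  expect_equal(unname(ic$codings[, "M2"]), c(-1, 0, 1))
  expect_equal(impute_and_code(ic, center = TRUE)$codings, ic$codings)
  expect_equal(impute_and_code(im)$codings, im$codings)

  M[, 2] <- NA
  expect_error(impute_and_code(genotype_matrix(M)), "M2")
})

test_that("LD pruning removes duplicates, keeps orthogonal markers, matches a greedy oracle", {
  set.seed(7)
  n <- 40
  base <- rbinom(n, 2, 0.4)
  M <- cbind(M1 = base, M2 = base, M3 = rbinom(n, 2, 0.4))
  map <- tibble::tibble(marker = colnames(M), chrom = "1",
                        pos = c(1L, 1001L, 2001L))
  gm <- genotype_matrix(M, map = map, imputed = TRUE)
  kept <- ld_prune(gm, 0.2, window = 10000, step = 5000)
  expect_length(intersect(kept, c("M1", "M2")), 1L)   # r^2 = 1 pair pruned
  expect_true("M3" %in% kept)

  # orthogonal centred columns all survive (exactly zero correlation)
  Mo <- qr.Q(qr(scale(matrix(rnorm(5 * 3), 5, 3), center = TRUE,
                      scale = FALSE)))[, 1:3]
  colnames(Mo) <- paste0("O", 1:3); rownames(Mo) <- paste0("S", 1:5)
  gmo <- genotype_matrix(Mo, map = tibble::tibble(
    marker = colnames(Mo), chrom = "1", pos = c(1L, 2L, 3L)), imputed = TRUE)
  expect_equal(ld_prune(gmo, 0.2, 100, 50), colnames(Mo))

  # 5-marker chain vs an exhaustive greedy oracle in one window
  gm5 <- rand_gm(60, 5, 42)
  # induce LD chain
  M5 <- gm5$codings
  M5[, 2] <- ifelse(runif(60) < 0.8, M5[, 1], M5[, 2])
  M5[, 3] <- ifelse(runif(60) < 0.6, M5[, 2], M5[, 3])
  gm5 <- genotype_matrix(M5, map = gm5$map, imputed = TRUE)
  greedy_oracle <- function(M, thr) {
    keep <- seq_len(ncol(M))
    maf <- apply(M, 2, function(x) {
      f <- (mean(x) - min(x)) / (max(x) - min(x)); min(f, 1 - f) })
    repeat {
      cc <- suppressWarnings(cor(M[, keep, drop = FALSE]))^2
      cc[!is.finite(cc)] <- 0; diag(cc) <- 0
      if (max(cc) <= thr) break
      v <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      a <- keep[v[1]]; b <- keep[v[2]]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      keep <- setdiff(keep, drop)
    }
    colnames(M)[keep]
  }
  expect_equal(ld_prune(gm5, 0.2, window = 100000, step = 100000),
               greedy_oracle(gm5$codings, 0.2))

  # invariance to sample order and marker scaling
  perm <- sample(nrow(gm5$codings))
  gm_p <- genotype_matrix(gm5$codings[perm, ], map = gm5$map, imputed = TRUE)
  gm_s <- genotype_matrix(sweep(gm5$codings, 2, c(1, 10, 0.5, 2, 7), `*`),
                          map = gm5$map, imputed = TRUE)
  ref <- ld_prune(gm5, 0.2, 100000, 100000)
  expect_equal(ld_prune(gm_p, 0.2, 100000, 100000), ref)
  expect_equal(ld_prune(gm_s, 0.2, 100000, 100000), ref)

  expect_error(ld_prune(genotype_matrix(M5, imputed = TRUE), 0.2), "map")
})

test_that("scan results round-trip through TSV at 12 significant digits", {
  res <- epiblup:::new_scan_result(tibble::tibble(
    marker = c("M1", "M2", "M3"),
    estimate = c(0.123456789012345, -2.5, NA),
    variance = c(0.01, 0.2, NA),
    statistic = c(1.23456789012345, -0.5, NA),
    df = 10L, p = c(0.2173, 1, NA),
    reason = c(NA, NA, "collinear")), "QK_P3D")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_results(res, f)
  back <- read_scan_results(f)
  expect_equal(nrow(back), 3L)                 # NA row retained
  expect_equal(back$neglog10p[2], 0)           # p = 1 -> neglog10p = 0
  expect_equal(back$estimate[1], res$estimate[1], tolerance = 1e-12)
  expect_equal(back$statistic[1], res$statistic[1], tolerance = 1e-12)
  expect_true(is.na(back$statistic[3]))
})
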