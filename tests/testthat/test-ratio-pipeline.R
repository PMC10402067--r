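test_that("depth normalization equalizes column depths and keeps proportions", {
  # equal-depth input passes through unchanged
  eq <- toy_counts(c(10, 20, 12, 18))
  expect_equal(depth_normalize(eq), eq)
  # second column at twice the depth is halved relative to the first
  cm <- toy_counts(c(5e5, 5e5, 1e6, 1e6))
  out <- depth_normalize(cm)
  expect_equal(sum(out$t_0), sum(out$t_10))
  expect_equal(out$t_10 / out$t_0, c(1, 1))
  expect_equal(out$t_0, c(7.5e5, 7.5e5))
  # all-zero column errors with the offending timepoint named
  z <- toy_counts(c(1, 2, 0, 0))
  expect_error(depth_normalize(z), "t_10")
})

test_that("HA columns are anchored to protein-level ratios", {
  myc <- toy_counts(c(10, 30, 10, 30))
  ha <- toy_counts(c(20, 60, 5, 15))
  flat <- tibble::tibble(time = c(0, 10), ratio = c(2, 0.5))
  out <- scale_ha_to_protein(ha, myc, flat)
  expect_equal(mean(out$t_0 / myc$t_0), 2)
  expect_equal(mean(out$t_10 / myc$t_10), 0.5)
  # protein ratio of exactly 1 at all times with matched signal: identity
  ones <- tibble::tibble(time = c(0, 10), ratio = c(1, 1))
  ha1 <- toy_counts(c(10, 30, 10, 30))
  expect_equal(scale_ha_to_protein(ha1, myc, ones), ha1)
  # a zero pre-induction protein level zeroes the HA column
  zero0 <- tibble::tibble(time = c(0, 10), ratio = c(0, 1))
  out0 <- scale_ha_to_protein(ha, myc, zero0)
  expect_equal(out0$t_0, c(0, 0))
  # missing timepoint is an error
  expect_error(scale_ha_to_protein(ha, myc,
                                   tibble::tibble(time = 0, ratio = 1)),
               "time point")
})

test_that("ratio table handles identity, pseudocount guard and shape checks", {
  m <- toy_counts(c(4, 8, 6, 2))
  r <- compute_ratio_table(m, m)
  expect_equal(r$R, rep(1, 4))
  expect_equal(sort(unique(r$time)), c(0, 10))
  # zero denominator guarded by pseudocount
  myc0 <- toy_counts(c(0, 8, 6, 2))
  expect_error(compute_ratio_table(m, myc0), "pseudocount")
  r2 <- compute_ratio_table(m, myc0, pseudocount = 1)
  expect_true(all(is.finite(r2$R)))
  expect_error(compute_ratio_table(m, toy_counts(c(1, 2), times = c(5, 15),
                                                 ids = "a")),
               "share")
})

test_that("three-step normalization reproduces generator truth without noise", {
  e <- simulate_experiment(25, seed = 41,
                           noise = noise_model(ratio_noise = 0),
                           sample_counts = FALSE)
  ha <- depth_normalize(e$ha_counts)
  myc <- depth_normalize(e$myc_counts)
  ha <- scale_ha_to_protein(ha, myc, e$protein_ratio)
  ratios <- compute_ratio_table(ha, myc)
  cmp <- dplyr::inner_join(ratios, e$ratio, by = c("site_id", "time"))
  expect_equal(cmp$R.x, cmp$R_true, tolerance = 1e-10)
  # the protein-scaling factor exactly undoes the residual per-column
  # distortion left after depth normalization (truth round trip)
  raw_ratio <- compute_ratio_table(depth_normalize(e$ha_counts), myc) |>
    dplyr::rename(R_raw = "R")
  fac <- raw_ratio |>
    dplyr::inner_join(dplyr::select(e$ratio, "site_id", "time", "R_true"),
                      by = c("site_id", "time")) |>
    dplyr::inner_join(dplyr::rename(ratios, R_final = "R"),
                      by = c("site_id", "time")) |>
    dplyr::group_by(time) |>
    dplyr::summarise(residual = mean(R_raw / R_true),
                     applied = mean(R_final / R_raw))
  expect_equal(fac$residual * fac$applied, rep(1, nrow(fac)),
               tolerance = 0.02)
})

test_that("ratio table is invariant to common per-timepoint count scalings", {
  e <- simulate_experiment(10, seed = 8, sample_counts = FALSE)
  scale_cols <- function(m, f) { m[-1] <- purrr::map2(m[-1], f, `*`); m }
  f <- c(2, 0.5, 1, 3, 1, 1, 0.25, 1, 10)
  chain <- function(ha, myc) {
    ha <- depth_normalize(ha); myc <- depth_normalize(myc)
    compute_ratio_table(scale_ha_to_protein(ha, myc, e$protein_ratio), myc)
  }
  r1 <- chain(e$ha_counts, e$myc_counts)
  r2 <- chain(scale_cols(e$ha_counts, f), scale_cols(e$myc_counts, f))
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
})

test_that("promoter-window assignment applies window, nearest and tRNA rules", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB", "gT"),
    chrom = "chrI",
    tss = c(10000L, 20000L, 30000L),
    strand = c("+", "-", "+"),
    biotype = c("mRNA", "mRNA", "tRNA")
  )
  mk <- function(mid) tibble::tibble(chrom = "chrI", start = mid - 50,
                                     end = mid + 50)
  regions <- dplyr::bind_rows(
    mk(10000 - 1 - 250),  # exactly 250 bp upstream of gA (+): kept
    mk(10000 - 1 - 251),  # 251 bp upstream: outside the window
    mk(10000 - 1 + 30),   # 30 bp downstream of gA: closer, wins over 250
    mk(20000 - 1 + 80),   # 80 bp upstream of gB (- strand): kept
    mk(20000 - 1 - 150),  # 150 bp downstream of gB (- strand): off-window
    mk(30000 - 1),        # at the tRNA TSS: removed by biotype
    mk(25000)             # between genes, outside every window
  )
  regions$site_id <- sprintf("r%d", seq_len(nrow(regions)))
  out <- assign_regions_to_genes(regions, ann)
  expect_identical(out$site_id, c("r3", "r4"))
  expect_identical(out$gene_id, c("gA", "gB"))
  expect_equal(out$distance, c(30, -80))
  # malformed interval reports the line
  bad <- regions; bad$end[2] <- bad$start[2]
  expect_error(assign_regions_to_genes(bad, ann), "line 2")
})

test_that("assignment is strand-symmetric under coordinate mirroring", {
  e <- simulate_experiment(40, seed = 17)
  out <- assign_regions_to_genes(e$regions, e$annotation)
  L <- 1e6
  mirror_regions <- e$regions |>
    dplyr::mutate(start2 = L - end, end = L - start,
                  start = start2) |>
    dplyr::select(-"start2")
  mirror_ann <- e$annotation |>
    dplyr::mutate(tss = L - (tss - 1) + 1,
                  strand = ifelse(strand == "+", "-", "+"))
  out_m <- assign_regions_to_genes(mirror_regions, mirror_ann)
  expect_identical(out$site_id, out_m$site_id)
  expect_identical(out$gene_id, out_m$gene_id)
  expect_equal(out$distance, out_m$distance)
})
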