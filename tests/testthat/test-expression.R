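# Delta-Ct normalisation, fold changes, preferential and treatment calls.

ct_fixture <- function(ct_by_gene_cond, replicates = 3, refs = "REF") {
  # ct_by_gene_cond: named list gene -> named vector condition -> Ct
  rows <- do.call(rbind, lapply(names(ct_by_gene_cond), function(g)
    do.call(rbind, lapply(names(ct_by_gene_cond[[g]]), function(cond)
      data.frame(gene = g, condition = cond, replicate = seq_len(replicates),
                 ct = ct_by_gene_cond[[g]][[cond]],
                 stringsAsFactors = FALSE)))))
  ct_table(rows, reference_genes = refs)
}

test_that("delta-Ct and relative expression follow the closed form", {
  tab <- ct_fixture(list(REF = c(t1 = 20), g = c(t1 = 25)))
  d <- delta_ct(tab)
  expect_equal(unique(d$delta_ct), 5)
  expect_equal(unique(d$rel_expr), 2^-5)
  # gene at reference level: delta-Ct 0, expression 1
  tab2 <- ct_fixture(list(REF = c(t1 = 20), g = c(t1 = 20)))
  expect_equal(unique(delta_ct(tab2)$rel_expr), 1)
})

test_that("multiple reference genes are averaged per replicate", {
  tab <- ct_fixture(list(R1 = c(t1 = 18), R2 = c(t1 = 22), g = c(t1 = 25)),
                    refs = c("R1", "R2"))
  expect_equal(unique(delta_ct(tab)$delta_ct), 5)  # reference mean 20
})

test_that("fold change is exact on the noise-free fixture and antisymmetric", {
  tab <- ct_fixture(list(REF = c(mock = 20, trt = 20),
                         g = c(mock = 30, trt = 28)))
  fc <- fold_change(tab, "trt", "mock")
  expect_equal(fc$fold_change, 4)     # delta-delta-Ct of 2 cycles
  expect_equal(fc$call, "up")
  fc_rev <- fold_change(tab, "mock", "trt")
  expect_equal(fc_rev$fold_change, 1 / 4)
  expect_equal(fc_rev$call, "down")
})

test_that("a large fold change without significance stays unchanged", {
  # high replicate variance swamps a 1.9-fold shift
  rows <- data.frame(
    gene = rep(c("REF", "g"), each = 6),
    condition = rep(rep(c("mock", "trt"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(rep(20, 6), 30 + c(-4, 0, 4), 29.07 + c(4, 0, -4)),
    stringsAsFactors = FALSE)
  fc <- fold_change(ct_table(rows, "REF"), "trt", "mock")
  expect_gt(fc$fold_change, 1.5)
  expect_gt(fc$p_value, 0.05)
  expect_equal(fc$call, "unchanged")
})

test_that("the 1.2-fold / 0.05 joint rule drives the calls", {
  tab <- make_ct_table(paste0("g", 1:3), c("mock", "trt"), replicates = 4,
                       log2_effects = matrix(c(0, 0, 0,
                                               1, -1, 0.1), 3, 2),
                       noise_sd = 0.05, seed = 71)
  fc <- fold_change(tab, "trt", "mock")
  expect_equal(fc$call, c("up", "down", "unchanged"))
  fc_bh <- fold_change(tab, "trt", "mock", adjust = TRUE)
  expect_true("p_adj" %in% names(fc_bh))
  expect_true(all(fc_bh$p_adj >= fc_bh$p_value))
})

test_that("preferential expression needs >2-fold against EVERY other tissue", {
  # 8-fold higher in flower than everywhere else
  tab <- make_ct_table("g", c("root", "stem", "leaf", "flower"),
                       replicates = 3,
                       log2_effects = matrix(c(0, 0, 0, 3), 1, 4),
                       noise_sd = 0.05, seed = 81)
  call <- preferential_call(tab, "g")
  expect_equal(call$tissue, "flower")
  expect_equal(nrow(call$pairs), 12)  # all ordered tissue pairs

  # flat expression: no tissue qualifies
  flat <- make_ct_table("g", c("root", "stem", "leaf"), replicates = 3,
                        noise_sd = 0.05, seed = 82)
  expect_true(is.na(preferential_call(flat, "g")$tissue))

  # 3-fold over root but only ~1.5-fold over stem: the for-all rule fails
  part <- make_ct_table("g", c("root", "stem", "flower"), replicates = 3,
                        log2_effects = matrix(c(0, log2(2), log2(3)), 1, 3),
                        noise_sd = 0.05, seed = 83)
  expect_true(is.na(preferential_call(part, "g")$tissue))
})

test_that("at most one tissue can ever be preferential", {
  set.seed(91)
  for (i in 1:50) {
    eff <- matrix(rnorm(4, sd = 2), 1, 4)
    tab <- make_ct_table("g", paste0("t", 1:4), replicates = 3,
                         log2_effects = eff, noise_sd = 0.1, seed = 91 + i)
    call <- preferential_call(tab, "g")
    # recount winners independently from the pairwise table
    winners <- vapply(unique(call$pairs$tissue), function(t1) {
      sel <- call$pairs$tissue == t1
      all(call$pairs$fold_change[sel] > 2 & call$pairs$p_value[sel] < 0.05)
    }, TRUE)
    expect_lte(sum(winners), 1)
    if (sum(winners) == 1)
      expect_equal(call$tissue, names(which(winners)))
  }
})

test_that("programmed effects are recovered without bias", {
  # mean of the log2 fold-change estimator over many genes per cell
  for (n in c(3, 6)) for (delta in c(0.26, 1, 2, 3)) {
    tab <- make_ct_table(paste0("g", 1:200), c("mock", "trt"),
                         replicates = n,
                         log2_effects = cbind(rep(0, 200), rep(delta, 200)),
                         noise_sd = 0.1, seed = round(1e4 + 100 * n + delta * 7))
    fc <- fold_change(tab, "trt", "mock")
    expect_lt(abs(mean(log2(fc$fold_change)) - delta), 3 * 0.1 / sqrt(n))
  }
})

test_that("near-threshold effects are detected at the expected rates", {
  # A programmed log2 effect of 0.26 sits marginally BELOW the call cutoff
  # log2(1.2) = 0.263, so with sigma = 0.05 and n = 3 the detection rate
  # hovers just under one half (the estimate must overshoot its own mean);
  # it must still far exceed the 5% null rate.
  tab <- make_ct_table(paste0("g", 1:100), c("mock", "trt"), replicates = 3,
                       log2_effects = cbind(rep(0, 100), rep(0.26, 100)),
                       noise_sd = 0.05, seed = 555)
  fc <- fold_change(tab, "trt", "mock")
  expect_gt(mean(fc$call == "up"), 0.15)
  # an effect clearly above the cutoff is called up in the majority
  tab2 <- make_ct_table(paste0("g", 1:100), c("mock", "trt"), replicates = 3,
                        log2_effects = cbind(rep(0, 100), rep(0.4, 100)),
                        noise_sd = 0.05, seed = 556)
  fc2 <- fold_change(tab2, "trt", "mock")
  expect_gt(mean(fc2$call == "up"), 0.5)
})

test_that("Ct table validation catches malformed input", {
  bad <- data.frame(gene = "g", condition = "a", replicate = 1, ct = 50)
  expect_error(ct_table(bad, "g"), "0, 45")
  rows <- data.frame(gene = rep(c("REF", "g"), each = 2),
                     condition = "a", replicate = c(1, 2, 1, 2),
                     ct = c(20, 20, 25, 25), stringsAsFactors = FALSE)
  expect_error(ct_table(rows, "missing"), "reference genes missing")
  expect_error(fold_change(ct_table(rows, "REF"), "a", "zz"), "not present")
})
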