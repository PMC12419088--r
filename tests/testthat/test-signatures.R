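# Step-by-step empirical-Bayes oracle for the moderated one-vs-rest test:
# ordinary pooled two-sample statistics, then inverse-gamma moment matching of
# the sample variances via the log-variance moments, independent of the
# implementation under test.
ebayes_oracle <- function(m, in_layer) {
  n1 <- rowSums(!is.na(m[, in_layer, drop = FALSE]))
  n0 <- rowSums(!is.na(m[, !in_layer, drop = FALSE]))
  m1 <- rowMeans(m[, in_layer, drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(m[, !in_layer, drop = FALSE], na.rm = TRUE)
  v1 <- apply(m[, in_layer, drop = FALSE], 1, var, na.rm = TRUE)
  v0 <- apply(m[, !in_layer, drop = FALSE], 1, var, na.rm = TRUE)
  df <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  # moment matching on z = log(s2): E z = log(s02) + digamma(d/2) - log(d/2)
  #                  (prior part)  + digamma(d0/2) - log(d0/2) contributions
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - mean(trigamma(df / 2))
  stopifnot(evar > 0)
  trig_inv <- function(y) {
    uniroot(function(x) trigamma(x) - y, c(1e-6, 1e8), tol = 1e-12)$root
  }
  d0 <- 2 * trig_inv(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  t <- (m1 - m0) / sqrt(s2_post * (1 / n1 + 1 / n0))
  p <- 2 * pt(abs(t), df + d0, lower.tail = FALSE)
  list(logFC = m1 - m0, t = t, p = p, d0 = d0, s02 = s02, s2 = s2,
       s2_post = s2_post)
}

make_toy_de <- function(seed = 42, n_prot = 20, effect_protein = "p01",
                        effect = 2) {
  set.seed(seed)
  man <- mini_manifest("E14.5", n_hemispheres = 3L)
  ctrl <- man[man$model == "CTRL", ]
  prot <- sprintf("p%02d", seq_len(n_prot))
  m <- matrix(rnorm(n_prot * nrow(ctrl), sd = 0.4), n_prot, nrow(ctrl),
              dimnames = list(prot, ctrl$sample_id))
  m[effect_protein, ctrl$layer_index == 1] <-
    m[effect_protein, ctrl$layer_index == 1] + effect
  full <- matrix(rnorm(n_prot * nrow(man), sd = 0.4), n_prot, nrow(man),
                 dimnames = list(prot, man$sample_id))
  full[, colnames(m)] <- m
  list(matrix = full, manifest = man, ctrl = ctrl)
}

test_that("with zero prior df the moderated test reduces to the ordinary pooled
           t-test", {
  d <- make_toy_de()
  tab <- moderated_layer_de(d$matrix, d$manifest, layer = 1, prior_df = 0)
  in_layer <- d$ctrl$layer_index == 1
  for (p in c("p01", "p05", "p17")) {
    tt <- t.test(d$matrix[p, d$ctrl$sample_id][in_layer],
                 d$matrix[p, d$ctrl$sample_id][!in_layer], var.equal = TRUE)
    row <- tab[tab$protein == p, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$logFC, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("equal group means give logFC 0 and t 0", {
  man <- mini_manifest("E14.5", 3L)
  ctrl <- man[man$model == "CTRL", ]
  # values depend only on the hemisphere, so every layer has the same mean
  m <- matrix(ave(seq_len(nrow(ctrl)), ctrl$hemisphere_id), nrow = 1,
              dimnames = list("p1", ctrl$sample_id))
  full <- matrix(0, 1, nrow(man), dimnames = list("p1", man$sample_id))
  full[, colnames(m)] <- m
  tab <- moderated_layer_de(full, man, layer = 2, prior_df = 0)
  expect_equal(tab$logFC, 0)
  expect_equal(tab$t, 0)
})

test_that("a planted 2-log2FC protein ranks first and matches the hand-rolled
           empirical-Bayes oracle", {
  d <- make_toy_de()
  tab <- moderated_layer_de(d$matrix, d$manifest, layer = 1)
  expect_equal(tab$protein[1], "p01")
  expect_gt(tab$logFC[tab$protein == "p01"], 1.5)

  orc <- ebayes_oracle(d$matrix[, d$ctrl$sample_id], d$ctrl$layer_index == 1)
  idx <- match(tab$protein, names(orc$t))
  expect_equal(tab$t, unname(orc$t[idx]), tolerance = 1e-6)
  expect_equal(tab$p, unname(orc$p[idx]), tolerance = 1e-6)
  # posterior variances are convex combinations: between sample and prior
  lo <- pmin(orc$s2, orc$s02); hi <- pmax(orc$s2, orc$s02)
  expect_true(all(orc$s2_post >= lo - 1e-12 & orc$s2_post <= hi + 1e-12))
})

test_that("the moderated statistics agree with limma on complete data", {
  d <- make_toy_de(seed = 7)
  ctrl <- d$ctrl
  tab <- moderated_layer_de(d$matrix, d$manifest, layer = 1)
  design <- cbind(1, as.integer(ctrl$layer_index == 1))
  fit <- limma::eBayes(limma::lmFit(d$matrix[, ctrl$sample_id], design))
  idx <- match(tab$protein, rownames(d$matrix))
  expect_equal(tab$t, unname(fit$t[idx, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[idx, 2]), tolerance = 1e-8)
  expect_equal(tab$logFC, unname(fit$coefficients[idx, 2]), tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up construction", {
  set.seed(9)
  for (rep in 1:5) {
    p <- runif(sample(5:20, 1))
    n <- length(p)
    o <- order(p)
    manual <- numeric(n)
    prev <- 1
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      manual[o[i]] <- prev
    }
    expect_equal(p.adjust(p, "BH"), manual, tolerance = 1e-12)
  }
  d <- make_toy_de()
  tab <- moderated_layer_de(d$matrix, d$manifest, layer = 1)
  expect_true(all(tab$adj_p >= tab$p))
})

# --- unique top-k signatures ----------------------------------------------

fake_table <- function(layer, proteins, logFC, p = 0.01) {
  structure(data.frame(protein = proteins, layer = layer, logFC = logFC,
                       t = logFC * 10, df = 10, p = p, adj_p = p,
                       stringsAsFactors = FALSE),
            class = c("differential_table", "data.frame"))
}

test_that("already-disjoint top-10 lists pass through unchanged", {
  t1 <- fake_table(1, sprintf("A%02d", 1:12), seq(12, 1))
  t2 <- fake_table(2, sprintf("B%02d", 1:12), seq(12, 1))
  sig <- unique_top_signatures(list(t1, t2))
  expect_equal(sig$protein[sig$layer == 1], sprintf("A%02d", 1:10))
  expect_equal(sig$protein[sig$layer == 2], sprintf("B%02d", 1:10))
})

test_that("a protein claimed by an earlier layer is skipped by later layers", {
  t1 <- fake_table(1, sprintf("P%02d", 1:10), seq(10, 1))
  t2 <- fake_table(2, c("P01", sprintf("P%02d", 11:20)), seq(11, 1))
  sig <- unique_top_signatures(list(t1, t2))
  expect_equal(sig$protein[sig$layer == 2], sprintf("P%02d", 11:20))
  expect_false("P01" %in% sig$protein[sig$layer == 2])
})

test_that("layers with few eligible proteins yield short signatures and only
           positive significant proteins are candidates", {
  t1 <- fake_table(1, sprintf("P%02d", 1:10), seq(10, 1))
  t2 <- fake_table(2, c(sprintf("P%02d", 7:10), "Q1", "Q2", "Q3", "Q4", "N1", "N2"),
                   c(10:7, 4:1, 5, 5),
                   p = c(rep(0.01, 8), 0.5, 0.01))
  t2$logFC[t2$protein == "N2"] <- -3  # high |t| but downregulated
  sig <- unique_top_signatures(list(t1, t2))
  expect_equal(sort(sig$protein[sig$layer == 2]), sort(c("Q1", "Q2", "Q3", "Q4")))
  expect_equal(nrow(sig[sig$layer == 2, ]), 4)
})

test_that("signatures are disjoint and the claim order is ascending layers", {
  # identical candidate lists in every layer: earlier layers claim top logFC
  tabs <- lapply(1:4, function(L) fake_table(L, sprintf("S%02d", 1:40), seq(40, 1)))
  sig <- unique_top_signatures(list(tabs[[3]], tabs[[1]], tabs[[4]], tabs[[2]]))
  expect_equal(nrow(sig), length(unique(sig$protein)))  # disjoint
  expect_equal(sig$protein[sig$layer == 1], sprintf("S%02d", 1:10))
  expect_equal(sig$protein[sig$layer == 4], sprintf("S%02d", 31:40))
  # first-come-first-serve is order dependent: layer 1 always wins S01
  expect_false("S01" %in% sig$protein[sig$layer > 1])
})

# --- correlation mapping ----------------------------------------------------

test_that("CTRL maps onto itself along the diagonal on clean data", {
  man <- mini_manifest("E14.5", 3L)
  sim <- simulate_abundance(clean_config(n_proteins = 120, noise_sd = 0.05),
                            man, seed = 3)
  tabs <- lapply(1:9, function(L)
    moderated_layer_de(sim$matrix, man, L, model = "CTRL", timepoint = "E14.5"))
  sig <- unique_top_signatures(tabs)
  mu <- layer_means(sim$matrix, man, "CTRL", "E14.5")
  map <- signature_correlation_map(sig, mu, mu)
  expect_equal(map$best_ref_layer, map$query_layer)
  expect_equal(map$best_r, rep(1, 9), tolerance = 1e-9)
})

test_that("tied correlation vectors resolve to the lowest reference layer", {
  sig <- structure(data.frame(layer = 1, rank = 1:3,
                              protein = c("a", "b", "c"),
                              logFC = 3:1, p = 0.01),
                   class = c("layer_signature", "data.frame"))
  ref <- matrix(c(1, 2, 3, 1, 2, 3, 5, 1, 4), 3,
                dimnames = list(c("a", "b", "c"), c("L1", "L2", "L3")))
  qry <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  map <- signature_correlation_map(sig, ref, qry)
  expect_equal(map$best_ref_layer, 1L)  # L1 and L2 tie at r = 1
  expect_equal(map$best_r, 1, tolerance = 1e-12)
})

test_that("zero-variance query vectors warn and yield NA assignments", {
  sig <- structure(data.frame(layer = 1, rank = 1:3,
                              protein = c("a", "b", "c"),
                              logFC = 3:1, p = 0.01),
                   class = c("layer_signature", "data.frame"))
  ref <- matrix(c(1, 2, 3, 3, 2, 1), 3,
                dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  qry <- matrix(c(2, 2, 2), 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  expect_warning(map <- signature_correlation_map(sig, ref, qry),
                 "no defined correlation")
  expect_true(is.na(map$best_ref_layer))
})

test_that("signature overlap counts identical, disjoint and planted-shared cases", {
  sig_a <- structure(data.frame(layer = rep(1:2, each = 3), rank = rep(1:3, 2),
                                protein = c("x1", "x2", "x3", "y1", "y2", "y3"),
                                logFC = 1, p = 0.01),
                     class = c("layer_signature", "data.frame"))
  sig_b <- sig_a
  ov <- signature_overlap(list(A = sig_a, B = sig_b))
  expect_true(all(ov$overlap == 3))
  sig_c <- sig_a
  sig_c$protein <- paste0("z", 1:6)
  ov2 <- signature_overlap(list(A = sig_a, C = sig_c))
  expect_true(all(ov2$overlap == 0))
  # shared superficial proteins, distinct deep proteins
  sig_d <- sig_a
  sig_d$protein[4:6] <- c("w1", "w2", "w3")
  ov3 <- signature_overlap(list(A = sig_a, D = sig_d))
  expect_gt(ov3$overlap[ov3$layer == 1][1], ov3$overlap[ov3$layer == 2][1])
})
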