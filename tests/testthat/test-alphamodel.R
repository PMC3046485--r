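test_that("pure-parent signals give the boundary share estimates", {
  A <- c(200, 150, 320, 90)
  T_ <- c(400, 380, 500, 260)
  S_a <- matrix(rep(A, 3), ncol = 3)
  S_t <- matrix(rep(T_, 3), ncol = 3)
  expect_equal(estimate_alpha(S_a, A, T_)$alpha, 1)
  expect_equal(estimate_alpha(S_t, A, T_)$alpha, 0)
  expect_error(estimate_alpha(S_a, T_, T_), "unidentifiable")
})

test_that("the closed form equals a brute-force SSE minimizer", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    A <- rlnorm(n, 5, 0.5)
    T_ <- rlnorm(n, 5.5, 0.5)
    alpha_true <- runif(1, -0.3, 1.3)
    S <- matrix(alpha_true * A + (1 - alpha_true) * T_, n, 3) +
      matrix(rnorm(3 * n, 0, 20), n, 3)
    fit <- estimate_alpha(S, A, T_)
    sse <- function(a) sum((S - a * A - (1 - a) * T_)^2)
    expect_lt(abs(fit$alpha - brute_force_minimize(sse)), 1e-8)
  }
})

test_that("alpha and X are invariant to joint rescaling of S, A, T", {
  set.seed(6)
  A <- rlnorm(5, 5); T_ <- rlnorm(5, 5)
  S <- matrix(0.4 * A + 0.6 * T_, 5, 3) + rnorm(15, 0, 5)
  F_ <- matrix(0.5 * A + 0.5 * T_, 5, 3) + rnorm(15, 0, 5)
  xs <- x_statistic(S, F_, A, T_)
  for (c_ in c(0.1, 7)) {
    xs2 <- x_statistic(c_ * S, c_ * F_, c_ * A, c_ * T_)
    expect_equal(xs2$alpha1, xs$alpha1)
    expect_equal(xs2$X, xs$X)
  }
  # swapping the parental roles maps alpha to 1 - alpha
  sw <- estimate_alpha(S, T_, A)
  expect_equal(sw$alpha, 1 - estimate_alpha(S, A, T_)$alpha)
  # exchanging the two samples leaves X unchanged
  ex <- x_statistic(F_, S, A, T_)
  expect_equal(ex$X, xs$X)
  expect_equal(ex$alpha1, xs$alpha2)
})

test_that("equal estimated shares give X = 0, p = 1", {
  A <- c(100, 150, 220); T_ <- c(300, 280, 400)
  S <- matrix(0.5 * A + 0.5 * T_, 3, 3)
  xs <- x_statistic(S, S, A, T_)
  expect_equal(xs$X, 0)
  expect_equal(xs$p_value, 1)
  expect_false(xs$degenerate)
  # noiseless samples with different shares: degenerate flag
  F_ <- matrix(0.8 * A + 0.2 * T_, 3, 3)
  xs2 <- x_statistic(S, F_, A, T_)
  expect_true(xs2$degenerate)
  expect_equal(xs2$p_value, 0)
})

test_that("X matches a term-wise independent re-derivation", {
  set.seed(7)
  n <- 3
  A <- rlnorm(n, 5); T_ <- rlnorm(n, 5)
  S <- matrix(0.3 * A + 0.7 * T_, n, 3) + rnorm(3 * n, 0, 3)
  F_ <- matrix(0.5 * A + 0.5 * T_, n, 3) + rnorm(3 * n, 0, 3)
  xs <- x_statistic(S, F_, A, T_)
  # oracle: flatten probes x replicates and accumulate sums term by term
  Af <- rep(A, 3); Tf <- rep(T_, 3); Sf <- as.vector(S); Ff <- as.vector(F_)
  a1 <- sum((Sf - Tf) * (Af - Tf)) / sum((Af - Tf)^2)
  a2 <- sum((Ff - Tf) * (Af - Tf)) / sum((Af - Tf)^2)
  num <- 0.5 * (a1 - a2)^2 * sum((Af - Tf)^2)
  den <- (sum((Sf - Tf - a1 * (Af - Tf))^2) +
            sum((Ff - Tf - a2 * (Af - Tf))^2)) / (6 * n - 1)
  expect_equal(xs$alpha1, a1)
  expect_equal(xs$alpha2, a2)
  expect_equal(xs$X, num / den)
  expect_equal(xs$df2, 6 * n - 1)
  expect_equal(xs$p_value, pf(num / den, 1, 6 * n - 1, lower.tail = FALSE))
})

test_that("the permutation cross-check broadly agrees with the F p-value", {
  set.seed(8)
  n <- 6
  A <- rlnorm(n, 5); T_ <- rlnorm(n, 5)
  S <- matrix(0.5 * A + 0.5 * T_, n, 3) + rnorm(3 * n, 0, 10)
  F_ <- matrix(0.5 * A + 0.5 * T_, n, 3) + rnorm(3 * n, 0, 10)
  p_perm <- alpha_permutation_test(S, F_, A, T_, n_perm = 400, seed = 1)
  p_f <- x_statistic(S, F_, A, T_)$p_value
  expect_gt(p_perm, 0)
  expect_lte(p_perm, 1)
  expect_lt(abs(p_perm - p_f), 0.25)
})

test_that("expression calls respect the intergenic background threshold", {
  co <- small_cohort()
  ec <- expression_call(co$pp)
  tr <- co$seqs$truth
  truth_expr <- tr$expressed[match(ec$gene_id, tr$gene_id)]
  # recovered fraction close to the planted fraction
  expect_lt(abs(mean(ec$expressed) - mean(truth_expr)), 0.05)
  expect_gt(mean(ec$expressed == truth_expr), 0.95)
  # monotonicity: raising the percentile never adds expressed genes
  stricter <- expression_call(co$pp, percentile = 0.999)
  expect_true(all(ec$expressed | !stricter$expressed))
  # fallback path
  gene_rows <- co$pp[!is.na(co$pp$gene_id), ]
  expect_error(expression_call(gene_rows), "fallback")
  fb <- expression_call(gene_rows, fallback = 1e9)
  expect_false(any(fb$expressed))
})

test_that("retention recovery on the simulated cohort is faithful", {
  co <- small_cohort()
  ret <- classify_retention(co$pp, co$dfres)
  tr <- co$seqs$truth[match(ret$gene_id, co$seqs$truth$gene_id), ]
  tested <- ret$status == "tested"
  expect_gt(sum(tested), 50)
  # deleted genes carry the expected labels
  del <- tested & tr$retention_state != "both"
  correct <- (tr$retention_state == "At_deleted" &
                ret$label == "Aa_like") |
    (tr$retention_state == "Aa_deleted" & ret$label == "At_like")
  expect_gte(mean(correct[del]), 0.8)
  # significant calls on retained genes are rare
  sig <- tested & ret$label != "not_significant"
  expect_lte(sum(tr$retention_state[sig] == "both"), 0.05 * sum(sig) + 1)
  # null genes centre on zero share shift
  null_delta <- ret$delta_alpha[tested & tr$retention_state == "both"]
  expect_lt(abs(mean(null_delta)),
            3 * sd(null_delta) / sqrt(length(null_delta)))
  # label invariants
  expect_true(all(ret$q_value[tested] >= ret$p_value[tested]))
  expect_true(all(ret$alpha1[ret$label %in% "Aa_like"] >
                    ret$alpha2[ret$label %in% "Aa_like"]))
})

test_that("expression shares track the planted transcript fractions", {
  co <- small_cohort()
  expb <- classify_expression(co$pp, co$dfres)
  tr <- co$seqs$truth
  ok <- expb$status == "tested"
  expect_gt(sum(ok), 30)
  truth_alpha <- tr$expression_alpha_true[match(expb$gene_id[ok],
                                                tr$gene_id)]
  expect_gte(cor(expb$alpha1[ok], truth_alpha, method = "spearman"), 0.9)
  # unexpressed genes are excluded and counted
  expect_gt(sum(expb$status == "not_expressed"), 0)
})

test_that("both expression DF modes run; the recomputed mode is stricter", {
  co <- small_cohort()
  a <- classify_expression(co$pp, co$dfres, df_mode = "parental")
  b <- classify_expression(co$pp, co$dfres, df_mode = "rna_dna")
  expect_lte(sum(b$status == "tested"), sum(a$status == "tested"))
})
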