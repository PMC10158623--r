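# Design generators: classical, space-filling and exchange-built optimal
# designs, with brute-force oracles on tiny instances.

test_that("quadratic model matrix: column count, origin row, hand expansion", {
  X <- matrix(c(0, 0, 0), nrow = 1)
  M <- quadratic_model_matrix(X)
  expect_equal(ncol(M), 10)  # 1 + 3 + 3 + 3
  expect_equal(unname(M[1, ]), c(1, rep(0, 9)))
  row <- quadratic_model_matrix(matrix(c(1, -1, 0.5), nrow = 1))
  expect_equal(unname(row[1, ]),
               c(1, 1, -1, 0.5, -1, 0.5, -0.5, 1, 1, 0.25))
  expect_equal(ncol(quadratic_model_matrix(matrix(0, 1, 2))), 6)
})

test_that("ccd: run counts, alpha, clipping, degenerate k = 2 identity", {
  d <- ccd(fix_space3(), center_replicates = 6)
  expect_equal(nrow(d$coded), 20)  # 8 cube + 6 axial + 6 centre
  expect_equal(d$meta$alpha, 8^(1 / 4), tolerance = 1e-12)
  expect_true(all(d$coded >= -1 & d$coded <= 1))  # clipped
  un <- ccd(fix_space3(), center_replicates = 0, clip = FALSE)
  expect_equal(max(abs(un$coded)), 8^(1 / 4), tolerance = 1e-12)
  # face-centred k = 2 with one centre point: the 3x3 grid
  d2 <- ccd(fix_space2(), center_replicates = 1, alpha_mode = "face")
  grid <- unique(as.data.frame(d2$coded))
  expect_equal(nrow(grid), 9)
  expect_setequal(grid[[1]], c(-1, 1, 0))
})

test_that("bbd: construction counts and edge-midpoint structure", {
  expect_equal(nrow(bbd(fix_space3(), 3)$coded), 15)
  expect_equal(nrow(bbd(fix_space3(), 12)$coded), 24)
  d <- bbd(fix_space3(), 3)
  noncentre <- d$coded[rowSums(d$coded != 0) > 0, ]
  expect_true(all(rowSums(noncentre == 0) == 1))
  expect_true(all(abs(noncentre[noncentre != 0]) == 1))
  expect_error(bbd(fix_space2()), "3 factors")
})

test_that("lhs: stratification, determinism, bounds", {
  d <- lhs_design(fix_space3(), n = 4, seed = 5)
  u <- (d$coded + 1) / 2
  for (j in 1:3)
    expect_equal(sort(floor(u[, j] * 4)), 0:3)  # one per quartile
  expect_identical(lhs_design(fix_space3(), n = 16, seed = 2)$coded,
                   lhs_design(fix_space3(), n = 16, seed = 2)$coded)
  expect_false(isTRUE(all.equal(
    lhs_design(fix_space3(), n = 16, seed = 2)$coded,
    lhs_design(fix_space3(), n = 16, seed = 3)$coded)))
  d16 <- lhs_design(fix_space3())
  expect_equal(nrow(d16$coded), 16)
  expect_true(all(d16$coded > -1 & d16$coded < 1))
})

linear_model <- function(x) cbind(1, as.matrix(x))

test_that("d-optimal matches exhaustive enumeration on a tiny instance", {
  space <- fix_space2()
  cand <- matrix(c(-1, -1, 1, 0, 0.5,
                   -1, 1, -1, 0.3, 0.9), ncol = 2)
  best <- -Inf
  for (i in seq_len(nrow(multisets(5, 3)))) {
    idx <- multisets(5, 3)[i, ]
    M <- crossprod(linear_model(cand[idx, , drop = FALSE]))
    d <- det(M)
    if (d > best) best <- d
  }
  got <- d_optimal(space, n = 3, candidates = cand, seed = 4,
                   model = linear_model)
  expect_equal(exp(got$meta$log_det), best, tolerance = 1e-9)
  # criterion path never decreases, end state is a fixed point of the scan
  expect_true(all(diff(got$meta$trace) >= 0))
})

test_that("d-optimal: paper-sized quadratic instance and determinism", {
  d <- d_optimal(fix_space3(), n = 16, seed = 1)
  expect_equal(nrow(d$coded), 16)
  expect_true(all(d$coded >= -1 & d$coded <= 1))
  d2 <- d_optimal(fix_space3(), n = 16, seed = 1)
  expect_identical(d$coded, d2$coded)
  # det(X'X) of the result matches the reported log-determinant
  M <- crossprod(quadratic_model_matrix(d))
  expect_equal(as.numeric(determinant(M)$modulus), d$meta$log_det,
               tolerance = 1e-9)
})

test_that("i-optimal matches enumeration and beats d-optimal on its criterion", {
  space <- fix_space2()
  cand <- matrix(c(-1, -1, 1, 0, 0.5,
                   -1, 1, -1, 0.3, 0.9), ncol = 2)
  quad <- as.matrix(expand.grid(seq(-1, 1, length.out = 11),
                                seq(-1, 1, length.out = 11)))
  W <- crossprod(linear_model(quad)) / nrow(quad)
  icrit <- function(idx) {
    M <- crossprod(linear_model(cand[idx, , drop = FALSE]))
    tryCatch(sum(diag(solve(M, W))), error = function(e) Inf)
  }
  ms <- multisets(5, 3)
  best <- min(apply(ms, 1, icrit))
  got <- i_optimal(space, n = 3, candidates = cand, seed = 4,
                   model = linear_model, grid_levels = 11)
  expect_equal(got$meta$i_value, best, tolerance = 1e-9)

  dopt <- d_optimal(space, n = 3, candidates = cand, seed = 4,
                    model = linear_model)
  idx_d <- match(apply(dopt$coded, 1, paste, collapse = ","),
                 apply(cand, 1, paste, collapse = ","))
  expect_lte(got$meta$i_value, icrit(idx_d))
  expect_identical(got$coded,
                   i_optimal(space, n = 3, candidates = cand, seed = 4,
                             model = linear_model, grid_levels = 11)$coded)
})

test_that("lhs-seeded d-optimal: subset, forced selection, dominance", {
  space <- fix_space3()
  d <- lhsd_plus_d_optimal(space, n = 12, n_lhs_candidates = 40, seed = 6)
  expect_equal(nrow(d$coded), 12)
  lhs_cand <- lhs_design(space, n = 40,
                         seed = substream_seed(6, "lhs"))$coded
  keys <- apply(lhs_cand, 1, paste, collapse = ",")
  expect_true(all(apply(d$coded, 1, paste, collapse = ",") %in% keys))
  # selection dominates the first-n LHS rows on the D criterion
  first_n <- crossprod(quadratic_model_matrix(lhs_cand[1:12, ]))
  ld_first <- determinant(first_n)
  expect_gte(d$meta$log_det,
             if (ld_first$sign > 0) as.numeric(ld_first$modulus) else -Inf)
  # forced selection returns the LHS itself
  forced <- lhsd_plus_d_optimal(space, n = 16, n_lhs_candidates = 16,
                                seed = 6)
  expect_equal(unname(forced$coded),
               unname(lhs_design(space, n = 16,
                                 seed = substream_seed(6, "lhs"))$coded))
})

test_that("coded/natural round trips are exact to 1e-12 for all generators", {
  space <- fix_space3()
  designs <- list(ccd(space), bbd(space, 3), lhs_design(space, 8, seed = 1),
                  d_optimal(space, n = 12, seed = 1),
                  i_optimal(space, n = 12, seed = 1),
                  lhsd_plus_d_optimal(space, n = 12, seed = 1))
  for (d in designs) {
    back <- natural_to_coded(as.matrix(d$natural), space)
    expect_equal(unname(back), unname(d$coded), tolerance = 1e-12)
    expect_true(all(as.matrix(d$natural) >=
                      matrix(space$lower, nrow(d$natural), 3, byrow = TRUE) - 1e-9))
    expect_true(all(as.matrix(d$natural) <=
                      matrix(space$upper, nrow(d$natural), 3, byrow = TRUE) + 1e-9))
  }
})

test_that("factor space validation names the offending factor", {
  expect_error(factor_space(c("a", "b"), c(1, 5), c(2, 5)), "b")
  expect_error(d_optimal(fix_space3(), n = 5), "at least")
})
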