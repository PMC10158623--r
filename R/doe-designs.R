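# Experimental-design generators over a bounded factor space: classical
# response-surface designs (CCD, BBD), Latin hypercube sampling, and
# exchange-built D-/I-optimal designs for a full quadratic model.

#' Factor space for design generation
#'
#' @param names factor names.
#' @param lower,upper numeric bounds (lower < upper elementwise).
#' @param units character vector of units (for file headers).
#' @return an object of class `factor_space`.
#' @export
factor_space <- function(names, lower, upper, units = rep("", length(names))) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper),
            length(units) == length(names))
  if (any(lower >= upper))
    stop("lower must be < upper for every factor: ",
         paste(names[lower >= upper], collapse = ", "))
  structure(list(names = as.character(names), lower = as.numeric(lower),
                 upper = as.numeric(upper), units = as.character(units)),
            class = "factor_space")
}

#' The three-factor space of the expansion study
#'
#' Initial glucose 5-60 mmol/L, initial glutamine 2-12 mmol/L, microcarrier
#' concentration 1-20 g/L.
#' @return a [factor_space()].
#' @export
default_factor_space <- function() {
  factor_space(c("c_Glc", "c_Gln", "c_MC"),
               lower = c(5, 2, 1), upper = c(60, 12, 20),
               units = c("mmol/L", "mmol/L", "g/L"))
}

#' Coded/natural coordinate maps
#'
#' Coded units place the factor bounds at -1 and +1.
#' @param x matrix or data frame of runs (rows) by factors (columns).
#' @param space a [factor_space()].
#' @return a matrix in the other coordinate system.
#' @export
coded_to_natural <- function(x, space) {
  x <- as.matrix(x)
  ctr <- (space$upper + space$lower) / 2
  half <- (space$upper - space$lower) / 2
  out <- sweep(sweep(x, 2, half, "*"), 2, ctr, "+")
  colnames(out) <- space$names
  out
}

#' @rdname coded_to_natural
#' @export
natural_to_coded <- function(x, space) {
  x <- as.matrix(x)
  ctr <- (space$upper + space$lower) / 2
  half <- (space$upper - space$lower) / 2
  out <- sweep(sweep(x, 2, ctr, "-"), 2, half, "/")
  colnames(out) <- space$names
  out
}

new_design <- function(type, coded, space, meta = list()) {
  coded <- as.matrix(coded)
  colnames(coded) <- space$names
  nat <- coded_to_natural(coded, space)
  structure(list(type = type, natural = as.data.frame(nat), coded = coded,
                 space = space, meta = meta),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat("<doe_design> type =", x$type, ",", nrow(x$coded), "runs x",
      ncol(x$coded), "factors\n")
  print(utils::head(round(x$natural, 4), 8))
  if (nrow(x$natural) > 8) cat("...\n")
  invisible(x)
}

#' Full quadratic model matrix
#'
#' Expands coded runs into the columns of a second-order response-surface
#' model: intercept, linear terms, two-way interactions (pairs in
#' lexicographic order) and pure quadratics — `1 + k + k(k-1)/2 + k` columns
#' for `k` factors.
#'
#' @param design a `doe_design` or a coded matrix.
#' @return the expanded model matrix.
#' @export
quadratic_model_matrix <- function(design) {
  x <- if (inherits(design, "doe_design")) design$coded else as.matrix(design)
  k <- ncol(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  for (i in seq_len(k)) cols[[nm[i]]] <- x[, i]
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      cols[[paste0(nm[i], ":", nm[j])]] <- x[, i] * x[, j]
  for (i in seq_len(k)) cols[[paste0(nm[i], "^2")]] <- x[, i]^2
  do.call(cbind, cols)
}

#' Central composite design
#'
#' Two-level factorial cube, 2k axial points at distance `alpha`, and
#' replicated centre points. The rotatable `alpha = (2^k)^(1/4)` exceeds the
#' coded bounds, so axial points are clipped to the bounds by default
#' (face-centred behaviour at the boundary); carrier concentrations below
#' the lower bound are physically meaningless.
#'
#' @param space a [factor_space()].
#' @param center_replicates number of centre points (default 6, which gives
#'   the classical 20-run design for k = 3).
#' @param alpha_mode `"rotatable"` or `"face"`.
#' @param clip clip axial points to the coded bounds (default TRUE).
#' @return a `doe_design`.
#' @export
#' @examples
#' nrow(ccd(default_factor_space())$coded) # 20
ccd <- function(space, center_replicates = 6,
                alpha_mode = c("rotatable", "face"), clip = TRUE) {
  alpha_mode <- match.arg(alpha_mode)
  k <- length(space$names)
  stopifnot(k >= 2, center_replicates >= 0)
  alpha <- if (alpha_mode == "rotatable") (2^k)^(1 / 4) else 1
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  ctr <- matrix(0, nrow = center_replicates, ncol = k)
  coded <- rbind(cube, axial, ctr)
  if (clip) coded <- pmin(pmax(coded, -1), 1)
  new_design("ccd", coded, space,
             meta = list(alpha = alpha, alpha_mode = alpha_mode,
                         center_replicates = center_replicates,
                         clipped = clip))
}

#' Box-Behnken design
#'
#' Midpoints of the cube edges (all pairs of factors at their +/-1 levels
#' with the remaining factors at 0) plus replicated centre points; for
#' k = 3 that is 12 edge runs. Requires k >= 3.
#'
#' @inheritParams ccd
#' @param center_replicates centre points; 3 gives the textbook 15-run
#'   design, 12 reproduces a 24-run variant.
#' @return a `doe_design`.
#' @export
bbd <- function(space, center_replicates = 3) {
  k <- length(space$names)
  if (k < 3) stop("Box-Behnken designs require at least 3 factors")
  runs <- list()
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    block <- matrix(0, nrow = 4, ncol = k)
    block[, i] <- pm[, 1]
    block[, j] <- pm[, 2]
    runs[[length(runs) + 1]] <- block
  }
  coded <- rbind(do.call(rbind, runs),
                 matrix(0, nrow = center_replicates, ncol = k))
  new_design("bbd", coded, space,
             meta = list(center_replicates = center_replicates))
}

#' Latin hypercube design
#'
#' One run per equal-width stratum per factor: stratum order is a random
#' permutation and the position within each stratum is uniform.
#'
#' @param space a [factor_space()].
#' @param n number of runs (default 16, the size used when comparing against
#'   the optimal designs).
#' @param seed integer seed.
#' @return a `doe_design`.
#' @export
lhs_design <- function(space, n = 16, seed = 1L) {
  stopifnot(n >= 2)
  k <- length(space$names)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u01 <- sapply(seq_len(k), function(i) (sample(n) - runif(n)) / n)
  coded <- 2 * u01 - 1
  new_design("lhs", coded, space, meta = list(seed = seed, n = n))
}

# default candidate set for the exchange algorithms: full factorial grid with
# `levels` coded levels per factor
.candidate_grid <- function(k, levels = 5) {
  as.matrix(expand.grid(rep(list(seq(-1, 1, length.out = levels)), k)))
}

# Fedorov-style first-improvement exchange over a finite candidate set.
# crit(M) is minimized, where M = t(X) %*% X of the model matrix.
.exchange <- function(cand_mm, n, crit, seed, max_retries = 50,
                      max_passes = 100) {
  nc <- nrow(cand_mm)
  p <- ncol(cand_mm)
  if (n < p) stop("n must be at least the number of model columns (", p, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  xtx <- function(idx) crossprod(cand_mm[idx, , drop = FALSE])
  value <- function(M) tryCatch(crit(M), error = function(e) Inf)

  idx <- NULL
  for (try in seq_len(max_retries)) {
    cand_idx <- sample(nc, n, replace = TRUE)
    if (is.finite(value(xtx(cand_idx)))) { idx <- cand_idx; break }
  }
  if (is.null(idx)) stop("could not find a non-singular starting design")

  cur <- value(xtx(idx))
  trace <- cur
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(nc)) {
        if (j == idx[i]) next
        prop <- idx; prop[i] <- j
        v <- value(xtx(prop))
        if (v < cur - 1e-10 * (1 + abs(cur))) {
          idx <- prop; cur <- v; improved <- TRUE
          trace <- c(trace, cur)
          break
        }
      }
    }
    if (!improved) break
  }
  list(idx = idx, value = cur, trace = trace)
}

#' D-optimal design by Fedorov exchange
#'
#' Selects `n` runs (with replication allowed) from a finite candidate set,
#' maximizing `det(X'X)` of the full quadratic model matrix via
#' first-improvement exchange in a fixed scan order; deterministic under
#' `seed`.
#'
#' @param space a [factor_space()].
#' @param n number of runs (>= number of quadratic model columns; 10 for
#'   k = 3). Default 16.
#' @param candidates coded candidate matrix; default is a 5-level full
#'   factorial grid (125 candidates for k = 3).
#' @param seed integer seed for the starting design.
#' @param model model-matrix function of a coded matrix; default
#'   [quadratic_model_matrix()].
#' @return a `doe_design`; `meta$log_det` holds the achieved
#'   `log det(X'X)` and `meta$trace` the accepted criterion path.
#' @export
d_optimal <- function(space, n = 16, candidates = NULL, seed = 1L,
                      model = quadratic_model_matrix) {
  k <- length(space$names)
  if (is.null(candidates)) candidates <- .candidate_grid(k)
  colnames(candidates) <- space$names
  mm <- model(candidates)
  crit <- function(M) {
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) return(Inf)
    -as.numeric(d$modulus)
  }
  ans <- .exchange(mm, n, crit, seed)
  new_design("d_optimal", candidates[ans$idx, , drop = FALSE], space,
             meta = list(seed = seed, log_det = -ans$value,
                         trace = -ans$trace, n_candidates = nrow(candidates)))
}

#' I-optimal design by exchange
#'
#' Minimizes the average scaled prediction variance
#' `tr((X'X)^{-1} W)` of the quadratic model, where `W` is the moment matrix
#' of the model over a quadrature grid of the coded space.
#'
#' @inheritParams d_optimal
#' @param grid_levels quadrature grid resolution per factor (default 11).
#' @return a `doe_design`; `meta$i_value` holds the achieved criterion.
#' @export
i_optimal <- function(space, n = 16, candidates = NULL, seed = 1L,
                      model = quadratic_model_matrix, grid_levels = 11) {
  k <- length(space$names)
  if (is.null(candidates)) candidates <- .candidate_grid(k)
  colnames(candidates) <- space$names
  mm <- model(candidates)
  quad <- .candidate_grid(k, grid_levels)
  fg <- model(quad)
  W <- crossprod(fg) / nrow(fg)
  crit <- function(M) sum(diag(solve(M, W)))
  ans <- .exchange(mm, n, crit, seed)
  new_design("i_optimal", candidates[ans$idx, , drop = FALSE], space,
             meta = list(seed = seed, i_value = ans$value,
                         trace = ans$trace, n_candidates = nrow(candidates)))
}

#' Latin-hypercube-seeded D-optimal design
#'
#' A Latin hypercube generates the candidate set; D-optimal exchange then
#' selects `n` of its rows. With `n_lhs_candidates = n` the selection is
#' forced and the LHS itself is returned.
#'
#' @inheritParams d_optimal
#' @param n_lhs_candidates size of the LHS candidate set (>= n; default 64).
#' @return a `doe_design`.
#' @export
lhsd_plus_d_optimal <- function(space, n = 16, n_lhs_candidates = 64,
                                seed = 1L, model = quadratic_model_matrix) {
  stopifnot(n_lhs_candidates >= n)
  cand <- lhs_design(space, n = n_lhs_candidates,
                     seed = substream_seed(seed, "lhs"))$coded
  if (n_lhs_candidates == n) {
    # forced selection: the LHS is the design
    M <- crossprod(model(cand))
    ld <- determinant(M, logarithm = TRUE)
    d <- new_design("lhsd_d_optimal", cand, space,
                    meta = list(seed = seed,
                                log_det = if (ld$sign > 0)
                                  as.numeric(ld$modulus) else -Inf,
                                n_candidates = n))
    d$meta$n_lhs_candidates <- n_lhs_candidates
    return(d)
  }
  d <- d_optimal(space, n = n, candidates = cand,
                 seed = substream_seed(seed, "exchange"), model = model)
  d$type <- "lhsd_d_optimal"
  d$meta$n_lhs_candidates <- n_lhs_candidates
  d
}
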