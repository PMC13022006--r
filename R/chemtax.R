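#' Diagnostic pigment names
#'
#' The fifteen HPLC diagnostic pigments used by the chemotaxonomic
#' unmixing, in canonical column order. Chl a is last and anchors the
#' ratio matrices (every class has Chl a ratio 1).
#'
#' @return Character vector of pigment names.
#' @export
pigment_names <- function() {
  c("Chl b", "But Fuco", "Hex Fuco", "Allo", "Fuco", "Perid", "Zea",
    "DV Chl b", "Chl c1+c2", "Chl c3", "Lut", "Neo", "Viola", "Pras",
    "Chl a")
}

#' Microalgae class names
#' @return Character vector of the eight pigment-defined classes.
#' @export
microalgae_classes <- function() {
  c("Cyanobacteria1", "Cyanobacteria2", "Cyanobacteria4", "Prasinophytes3",
    "Cryptophytes", "Diatoms1", "Haptophytes6", "Dinoflagellates1")
}

.ratio_matrix <- function(values) {
  m <- matrix(values, nrow = 8, ncol = 15, byrow = TRUE,
              dimnames = list(microalgae_classes(), pigment_names()))
  m
}

#' Initial pigment:Chl a ratio matrix
#'
#' Literature-seeded pigment:chlorophyll-a weight ratios for the eight
#' microalgae classes; the starting point of the ratio-matrix search.
#' Cyanobacteria1 is filamentous colonial cyanobacteria (Trichodesmium and
#' relatives), Cyanobacteria2 mainly Synechococcus, Cyanobacteria4 mainly
#' Prochlorococcus; the zero pattern (e.g. peridinin only in
#' Dinoflagellates1) is structural and preserved by all operations.
#'
#' @return 8 x 15 numeric matrix, classes x pigments.
#' @export
ratio_matrix_initial <- function() {
  .ratio_matrix(c(
    # Chlb  ButF  HexF  Allo  Fuco  Perid Zea   DVChlb c12   c3    Lut   Neo   Viola Pras  Chla
    0,     0,    0,    0,    0,    0,    0.105, 0,    0,    0,    0,    0,    0,    0,    1,
    0,     0,    0,    0,    0,    0,    0.453, 0,    0,    0,    0,    0,    0,    0,    1,
    0.495, 0,    0,    0,    0,    0,    0.224, 0.495, 0,   0,    0,    0,    0,    0,    1,
    0.368, 0,    0,    0,    0,    0,    0.033, 0,    0,    0,    0.013, 0.051, 0.035, 0.145, 1,
    0,     0,    0,    0.359, 0,   0,    0,     0,    0.145, 0,   0,    0,    0,    0,    1,
    0,     0,    0,    0,    0.711, 0,   0,     0,    0.074, 0,   0,    0,    0,    0,    1,
    0,     0.004, 0.237, 0,  0.066, 0,   0,     0,    0.178, 0.156, 0,  0,    0,    0,    1,
    0,     0,    0,    0,    0,    0.541, 0,    0,    0.197, 0,   0,    0,    0,    0,    1))
}

#' Final pigment:Chl a ratio matrix
#'
#' The converged ratio matrix of the three-stage randomized search on the
#' study data; useful as a realistic generating matrix for simulations.
#'
#' @return 8 x 15 numeric matrix, classes x pigments.
#' @export
ratio_matrix_final <- function() {
  .ratio_matrix(c(
    0,     0,    0,    0,    0,    0,    0.101, 0,    0,    0,    0,    0,    0,    0,    1,
    0,     0,    0,    0,    0,    0,    1.343, 0,    0,    0,    0,    0,    0,    0,    1,
    0.432, 0,    0,    0,    0,    0,    0.203, 0.363, 0,   0,    0,    0,    0,    0,    1,
    0.605, 0,    0,    0,    0,    0,    0.035, 0,    0,    0,    0.013, 0.047, 0.035, 0.082, 1,
    0,     0,    0,    0.322, 0,   0,    0,     0,    0.129, 0,   0,    0,    0,    0,    1,
    0,     0,    0,    0,    0.609, 0,   0,     0,    0.098, 0,   0,    0,    0,    0,    1,
    0,     0.009, 0.488, 0,  0.096, 0,   0,     0,    0.215, 0.211, 0,  0,    0,    0,    1,
    0,     0,    0,    0,    0,    0.579, 0,    0,    0.236, 0,   0,    0,    0,    0,    1))
}

# Active-set non-negative least squares on the normal equations.
# AtA is shared across samples within one objective evaluation, which is
# what makes the ratio-matrix search affordable.
.nnls_normal <- function(AtA, Atb, tol = 1e-12) {
  k <- length(Atb)
  x <- numeric(k)
  P <- logical(k)
  scale <- max(diag(AtA), 1)
  tol <- tol * scale
  solveP <- function(P) {
    s <- numeric(k)
    m <- AtA[P, P, drop = FALSE]
    s[P] <- tryCatch(solve(m, Atb[P]),
                     error = function(e)
                       solve(m + diag(1e-10 * scale, sum(P)), Atb[P]))
    s
  }
  for (outer in seq_len(10 * k + 10)) {
    w <- Atb - drop(AtA %*% x)
    cand <- which(!P & w > tol)
    if (!length(cand)) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- solveP(P)
      neg <- P & s <= 0
      if (!any(neg)) { x <- s; break }
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
  }
  x
}

.pigment_weights <- function(S, weighting) {
  if (weighting == "none") return(rep(1, ncol(S)))
  rms <- sqrt(colMeans(S^2))
  w <- ifelse(rms > 0, 1 / rms, 0)
  w
}

.align_pigments <- function(S, F) {
  if (!is.matrix(S)) S <- as.matrix(S)
  if (!is.null(colnames(S)) && !is.null(colnames(F))) {
    if (!all(colnames(F) %in% colnames(S)))
      stop("pigment sets of samples and ratio matrix do not match")
    S <- S[, colnames(F), drop = FALSE]
  } else if (ncol(S) != ncol(F)) {
    stop("pigment dimension mismatch between samples and ratio matrix")
  }
  S
}

# Core solve: returns coefficients (n x k) and weighted RMS objective.
.ct_solve <- function(S, F, w) {
  Fw <- F * rep(w, each = nrow(F))
  Sw <- S * rep(w, each = nrow(S))
  AtA <- tcrossprod(Fw)
  AtB <- Fw %*% t(Sw)
  n <- nrow(S)
  C <- matrix(0, n, nrow(F), dimnames = list(rownames(S), rownames(F)))
  for (i in seq_len(n)) C[i, ] <- .nnls_normal(AtA, AtB[, i])
  resid <- Sw - C %*% Fw
  list(coef = C, objective = sqrt(mean(resid^2)))
}

#' Unmix pigment samples onto a ratio matrix
#'
#' Solves, per sample, a non-negativity-constrained least-squares fit of the
#' pigment concentration vector onto the class rows of the ratio matrix.
#' Because every class has Chl a ratio 1, the fitted coefficient of a class
#' is directly its chlorophyll-a contribution in ug chl a per litre. Pigment
#' columns are scaled by their root-mean-square over samples before fitting
#' (so abundant pigments do not dominate the objective); set
#' `weighting = "none"` to fit raw concentrations.
#'
#' @param S Samples x pigments concentration matrix (ug/L); column names
#'   must cover the ratio matrix's pigments.
#' @param F Classes x pigments ratio matrix, e.g. [ratio_matrix_initial()].
#' @param weighting `"rms"` (default) or `"none"`.
#' @return List with `contribution` (samples x classes, ug chl a/L),
#'   `percent` (rows summing to 100 where total chl a > 0) and `objective`
#'   (weighted root-mean-square residual over all cells).
#' @export
fit_composition <- function(S, F, weighting = c("rms", "none")) {
  weighting <- match.arg(weighting)
  S <- .align_pigments(S, F)
  if (any(S < 0, na.rm = TRUE)) stop("pigment concentrations must be >= 0")
  if (any(rowSums(S) == 0))
    warning("sample(s) with all-zero pigments: zero composition returned")
  w <- .pigment_weights(S, weighting)
  sol <- .ct_solve(S, F, w)
  tot <- rowSums(sol$coef)
  pct <- sol$coef
  pos <- tot > 0
  pct[pos, ] <- 100 * pct[pos, , drop = FALSE] / tot[pos]
  pct[!pos, ] <- 0
  list(contribution = sol$coef, percent = pct, objective = sol$objective)
}

#' Randomly perturb a ratio matrix
#'
#' Each nonzero, non-Chl-a entry is multiplied by (1 + u) with
#' u ~ Uniform(-magnitude, magnitude), independently per entry. Structural
#' zeros and the Chl a column are preserved; deterministic for a given
#' seed.
#'
#' @param F0 Ratio matrix.
#' @param magnitude Fractional perturbation half-width in [0, 1).
#' @param seed Optional integer seed.
#' @return Perturbed ratio matrix.
#' @export
perturb_ratio_matrix <- function(F0, magnitude = 0.35, seed = NULL) {
  if (magnitude < 0 || magnitude >= 1)
    stop("magnitude must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  F1 <- F0
  chla <- which(colnames(F0) == "Chl a")
  free <- F0 != 0
  if (length(chla)) free[, chla] <- FALSE
  n <- sum(free)
  F1[free] <- F0[free] * (1 + stats::runif(n, -magnitude, magnitude))
  F1
}

#' Bounded descent on the ratio matrix
#'
#' Accept-if-better single-entry multiplicative search: sweeps the nonzero
#' non-Chl-a entries in fixed order, proposing up/down multiplicative steps
#' and keeping a proposal only if the unmixing objective strictly
#' decreases. Entries are confined to [1-bound, 1+bound] times their value
#' in `F_init`; the Chl a column and structural zeros never move. Stops
#' after `max_iter` full sweeps or when the relative improvement over a
#' sweep falls below 1e-6.
#'
#' @param S Samples x pigments matrix.
#' @param F_init Starting ratio matrix (also defines the box bounds).
#' @param max_iter Maximum number of full sweeps.
#' @param bound Fractional box half-width around `F_init`.
#' @param step Multiplicative proposal step.
#' @param weighting Passed to the objective (see [fit_composition()]).
#' @return List with `F` (optimized matrix) and `trace` (objective after
#'   the initial evaluation and each sweep; non-increasing).
#' @export
optimize_ratio_matrix <- function(S, F_init, max_iter = 8, bound = 0.5,
                                  step = 0.1,
                                  weighting = c("rms", "none")) {
  weighting <- match.arg(weighting)
  S <- .align_pigments(S, F_init)
  w <- .pigment_weights(S, weighting)
  F <- F_init
  lo <- F_init * (1 - bound)
  hi <- F_init * (1 + bound)
  chla <- which(colnames(F) == "Chl a")
  free <- which(F_init != 0 & col(F_init) != if (length(chla)) chla else -1)
  obj <- .ct_solve(S, F, w)$objective
  trace <- obj
  if (max_iter > 0) {
    for (sweep in seq_len(max_iter)) {
      start <- obj
      for (idx in free) {
        cur <- F[idx]
        for (fac in c(1 + step, 1 / (1 + step))) {
          cand <- min(max(cur * fac, lo[idx]), hi[idx])
          if (cand == F[idx]) next
          Ftry <- F
          Ftry[idx] <- cand
          o <- .ct_solve(S, Ftry, w)$objective
          # strict descent beyond numerical noise, so a perfect fit is a
          # fixed point
          if (o < obj - 1e-10 * (1 + obj)) {
            F <- Ftry
            obj <- o
          }
        }
      }
      trace <- c(trace, obj)
      if (start - obj < 1e-6 * max(start, .Machine$double.eps)) break
    }
  }
  list(F = F, trace = trace, objective = obj)
}

#' Randomized multi-run ratio-matrix factorization
#'
#' The full chemotaxonomic procedure: per run, `n_random` randomly
#' perturbed copies of the current base matrix are each optimized by
#' [optimize_ratio_matrix()] and ranked by objective; the next run starts
#' from the element-wise mean of the `n_best` matrices. The defaults (3
#' runs of 60 random matrices, best-6 averaging) follow the standard
#' protocol. The returned composition is the unmixing under the best
#' matrix of the final run.
#'
#' @param S Samples x pigments matrix.
#' @param F0 Initial ratio matrix.
#' @param n_random Random matrices per run.
#' @param n_runs Number of runs.
#' @param n_best Matrices averaged to seed the next run (<= n_random).
#' @param magnitude Perturbation half-width (see [perturb_ratio_matrix()]).
#' @param bound,max_iter,step Passed to [optimize_ratio_matrix()].
#' @param weighting Objective weighting.
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @return List with `composition` (as [fit_composition()]), `F`
#'   (best final matrix) and `diagnostics` (best objective per run).
#' @export
chemtax_run <- function(S, F0, n_random = 60, n_runs = 3, n_best = 6,
                        magnitude = 0.35, bound = 0.5, max_iter = 8,
                        step = 0.1, weighting = c("rms", "none"),
                        seed = 1) {
  weighting <- match.arg(weighting)
  if (n_best > n_random) stop("n_best must be <= n_random")
  S <- .align_pigments(S, F0)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_runs * n_random)
  dim(sub_seeds) <- c(n_runs, n_random)
  F_base <- F0
  best_per_run <- numeric(n_runs)
  best_F <- F0
  best_obj <- Inf
  for (run in seq_len(n_runs)) {
    fits <- vector("list", n_random)
    objs <- numeric(n_random)
    for (j in seq_len(n_random)) {
      Fj <- perturb_ratio_matrix(F_base, magnitude, seed = sub_seeds[run, j])
      opt <- optimize_ratio_matrix(S, Fj, max_iter = max_iter, bound = bound,
                                   step = step, weighting = weighting)
      fits[[j]] <- opt$F
      objs[j] <- opt$objective
    }
    ord <- order(objs)  # ties broken by generation index
    # the incumbent best matrix is never discarded by a re-randomized run
    if (objs[ord[1]] < best_obj) {
      best_obj <- objs[ord[1]]
      best_F <- fits[[ord[1]]]
    }
    best_per_run[run] <- best_obj
    F_base <- Reduce(`+`, fits[ord[seq_len(n_best)]]) / n_best
  }
  comp <- fit_composition(S, best_F, weighting = weighting)
  list(composition = comp, F = best_F,
       diagnostics = list(best_objective_per_run = best_per_run))
}
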