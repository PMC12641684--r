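# Non-negative matrix factorization (multiplicative updates, Frobenius
# objective) and assembly of the seven classifier input configurations.

# ---- leakage guard ----------------------------------------------------
# Case ids registered as held-out must never reach a fit; any fit entry
# point checks its training rows against this registry and aborts.

.leakage <- new.env(parent = emptyenv())
.leakage$ids <- character(0)

#' Register / clear held-out case identifiers
#'
#' While ids are registered, any fitting routine (`nmf_fit`,
#' `nonneg_shift` via `fit_classifier`, classifier training) that receives
#' one of them among its training rows raises an error.
#'
#' @param ids character case identifiers.
#' @return Invisibly, the current registry.
#' @export
leakage_register <- function(ids) {
  .leakage$ids <- union(.leakage$ids, ids)
  invisible(.leakage$ids)
}

#' @rdname leakage_register
#' @export
leakage_clear <- function() {
  .leakage$ids <- character(0)
  invisible(character(0))
}

leakage_check <- function(ids, stage) {
  bad <- intersect(ids, .leakage$ids)
  if (length(bad))
    stop(sprintf("leakage guard: held-out case(s) %s reached %s",
                 paste(utils::head(bad, 3), collapse = ", "), stage))
  invisible(NULL)
}

# ---- NMF --------------------------------------------------------------

#' Fit NMF by multiplicative updates
#'
#' Minimizes the Frobenius error of `X ~ W H` with seeded uniform(0.1, 1]
#' initialization; the objective is recorded every iteration and is
#' non-increasing. Training scores are polished by the same fixed-basis
#' solver used by [nmf_transform()] so that transforming a training row
#' reproduces its score.
#'
#' @param X nonnegative cases x features matrix with rownames.
#' @param k number of components, `k <= min(dim(X))`.
#' @param iters multiplicative-update iterations.
#' @param seed initialization seed.
#' @return An `nmf_model`: `basis` (features x k), `scores` (training
#'   cases x k), `train_ids`, `objective_history`, `k`, `seed`.
#' @export
nmf_fit <- function(X, k, iters = 200L, seed = 1L) {
  if (any(X < 0)) stop("NMF requires nonnegative input")
  stopifnot(k >= 1, k <= min(dim(X)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("row_%d", seq_len(nrow(X)))
  leakage_check(rownames(X), "nmf_fit")
  n <- nrow(X); p <- ncol(X)
  eps <- 1e-10
  with_seed(seed, {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(X) / k + eps)
    H <- matrix(stats::runif(k * p, 0.1, 1), k, p) * sqrt(mean(X) / k + eps)
    obj <- numeric(iters)
    for (it in seq_len(iters)) {
      W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
      H <- H * (t(W) %*% X) / ((t(W) %*% W) %*% H + eps)
      obj[it] <- sqrt(sum((X - W %*% H)^2))
    }
    basis <- t(H)
    model <- structure(list(basis = basis, k = as.integer(k),
                            train_ids = rownames(X),
                            objective_history = obj,
                            seed = as.integer(seed)),
                       class = "nmf_model")
    # training scores come from the same deterministic fixed-basis
    # solver as nmf_transform, so transforming a training row
    # reproduces its score
    model$scores <- nmf_project(X, basis, iters = 500L)
    model
  })
}

# Fixed-basis nonnegative projection by multiplicative W-updates
# (deterministic: flat initialization unless W0 is given).
nmf_project <- function(X, basis, W0 = NULL, iters = 500L) {
  k <- ncol(basis)
  eps <- 1e-10
  W <- if (is.null(W0))
    matrix(mean(X) / (k * mean(basis) + eps) + eps, nrow(X), k) else W0
  HHt <- crossprod(basis)        # t(H) %*% ... = basis products
  XB <- X %*% basis
  for (it in seq_len(iters))
    W <- W * XB / (W %*% HHt + eps)
  rownames(W) <- rownames(X)
  W
}

#' Project new cases onto a fitted NMF basis
#'
#' Nonnegative least-squares scores against the frozen basis
#' (multiplicative updates on the scores only; the basis is never touched).
#'
#' @param model an `nmf_model`.
#' @param Xnew nonnegative matrix with the fitted feature count.
#' @param iters solver iterations.
#' @return Scores matrix (rows of `Xnew` x k).
#' @export
nmf_transform <- function(model, Xnew, iters = 500L) {
  stopifnot(inherits(model, "nmf_model"))
  if (any(Xnew < 0)) stop("NMF transform requires nonnegative input")
  if (ncol(Xnew) != nrow(model$basis))
    stop("column count does not match the fitted basis")
  nmf_project(Xnew, model$basis, iters = iters)
}

# ---- input configurations ---------------------------------------------

INPUT_CONFIG_NAMES <- c("radiomics_all", "radiomics_shape", "latent_seg",
                        "latent_vaegan", "latent_seg+vaegan",
                        "radiomics+latents", "shape+latents")

#' Reduce feature blocks on training cases and assemble the seven inputs
#'
#' Three sources are reduced to `k` dimensions each by NMF fit on the
#' training rows only (after a training-anchored nonnegative shift): the
#' full radiomics matrix, the segmentation-encoder latents (both scales
#' concatenated before one joint factorization), and the VAE latents. The
#' 14 shape features enter un-reduced. The seven configurations are the
#' cartesian building blocks used throughout: radiomics alone, shape
#' alone, each latent set, and their combinations.
#'
#' @param blocks list with `feature_block`s: `radiomics_all`, `shape`,
#'   `seg_full`, optionally `seg_half`, and `vaegan` (identical case sets).
#' @param train_ids case ids used for every fit.
#' @param k NMF dimensionality per source.
#' @param seed NMF seed.
#' @param nmf_iters multiplicative-update iterations.
#' @param configurations configuration names to assemble (default all 7);
#'   sources no requested configuration uses are not factorized.
#' @return List of `input_configuration`s: `name`, `matrix` (all cases),
#'   `blocks` (source names), `width`.
#' @export
reduce_and_configure <- function(blocks, train_ids, k = 16L, seed = 1L,
                                 nmf_iters = 150L,
                                 configurations = INPUT_CONFIG_NAMES) {
  need <- c("radiomics_all", "shape", "seg_full", "vaegan")
  stopifnot(all(need %in% names(blocks)),
            all(configurations %in% INPUT_CONFIG_NAMES))
  ids <- rownames(blocks$radiomics_all$matrix)
  for (b in blocks)
    if (!identical(rownames(b$matrix), ids))
      stop("alignment error: blocks cover different case sets")
  seg_mat <- blocks$seg_full$matrix
  if (!is.null(blocks$seg_half))
    seg_mat <- cbind(seg_mat, blocks$seg_half$matrix)
  colnames(seg_mat) <- sprintf("seg_%05d", seq_len(ncol(seg_mat)))
  sources <- list(radiomics = blocks$radiomics_all$matrix,
                  seg = seg_mat, vaegan = blocks$vaegan$matrix)
  cfg_sources <- list(
    radiomics_all = "radiomics", radiomics_shape = character(0),
    latent_seg = "seg", latent_vaegan = "vaegan",
    `latent_seg+vaegan` = c("seg", "vaegan"),
    `radiomics+latents` = c("radiomics", "seg", "vaegan"),
    `shape+latents` = c("seg", "vaegan"))
  wanted <- unique(unlist(cfg_sources[configurations]))
  scores <- list()
  for (nm in intersect(names(sources), wanted)) {
    fb <- feature_block(sources[[nm]], "latent")
    sh <- nonneg_shift(fb, train_ids)
    tr <- sh$matrix[rownames(sh$matrix) %in% train_ids, , drop = FALSE]
    fit <- nmf_fit(tr, k = k, iters = nmf_iters,
                   seed = seed + match(nm, names(sources)))
    sc <- nmf_transform(fit, sh$matrix)
    colnames(sc) <- sprintf("%s_nmf_%03d", nm, seq_len(k))
    scores[[nm]] <- sc
  }
  shape <- blocks$shape$matrix
  assemble <- function(nm) {
    M <- switch(nm,
                radiomics_all = scores$radiomics,
                radiomics_shape = shape,
                latent_seg = scores$seg,
                latent_vaegan = scores$vaegan,
                `latent_seg+vaegan` = cbind(scores$seg, scores$vaegan),
                `radiomics+latents` = cbind(scores$radiomics, scores$seg,
                                            scores$vaegan),
                `shape+latents` = cbind(shape, scores$seg, scores$vaegan))
    src <- if (nm == "radiomics_shape") "shape" else
      unique(c(if (grepl("^shape", nm)) "shape", cfg_sources[[nm]]))
    structure(list(name = nm, matrix = M, blocks = src, width = ncol(M)),
              class = "input_configuration")
  }
  out <- lapply(configurations, assemble)
  names(out) <- configurations
  out
}
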