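#' Fit an empirical-Bayes location/scale batch model (ComBat-style)
#'
#' Standardises each probe by its grand mean and pooled variance, estimates
#' per-(batch, probe) location and scale parameters, shrinks them towards
#' batch-level priors (normal for locations, inverse-gamma for scales,
#' hyperparameters by method of moments across probes), and solves the
#' shrunken estimates by the standard conditional-posterior fixed-point
#' iteration.
#'
#' @param beta Beta tibble (`probe_id` + sample columns).
#' @param sheet Sample sheet with `sample_id` and a batch column.
#' @param batch Name of the batch column in `sheet` (default "batch").
#' @param tol Relative convergence tolerance of the fixed-point iteration.
#' @param max_iter Maximum fixed-point iterations per batch.
#' @return An object of class `epi_combat`. Zero-variance probes are
#'   flagged and passed through uncorrected by [apply_combat()]. With a
#'   single batch the model is the identity.
#' @seealso [apply_combat()], [correct_batch()]
#' @export
fit_combat <- function(beta, sheet, batch = "batch", tol = 1e-4,
                       max_iter = 500) {
  X <- beta_matrix(beta)
  bvec <- sheet[[batch]][match(colnames(X), sheet$sample_id)]
  if (anyNA(bvec)) abort("every sample column must appear in the sample sheet")
  bfac <- factor(bvec)
  nb <- table(bfac)
  if (any(nb < 2) && nlevels(bfac) > 1) {
    abort(paste0("batch with a single sample (variance undefined): ",
                 paste(names(nb)[nb < 2], collapse = ", ")))
  }
  n <- ncol(X)
  if (nlevels(bfac) < 2) {
    return(structure(list(identity = TRUE, probe_id = rownames(X),
                          batches = levels(bfac), tol = tol),
                     class = "epi_combat"))
  }

  sd_all <- row_sds(X)
  zero_var <- sd_all <= 0 | !is.finite(sd_all)
  cols <- split(seq_len(n), bfac)
  batch_means <- vapply(cols, function(j) rowMeans(X[, j, drop = FALSE]),
                        numeric(nrow(X)))
  w <- as.numeric(nb) / n
  grand <- as.numeric(batch_means %*% w)
  fitted <- batch_means[, as.integer(bfac), drop = FALSE]
  var_pooled <- rowSums((X - fitted)^2) / n
  # probes varying only between batches: the batch effect is the whole
  # signal, so correction collapses them to the grand mean
  pure_batch <- !zero_var & (var_pooled <= 0 | !is.finite(var_pooled))
  eb_ok <- !zero_var & !pure_batch
  vp <- ifelse(eb_ok, var_pooled, 1)
  S <- (X - grand) / sqrt(vp)

  B <- nlevels(bfac)
  g_hat <- g_star <- d_hat <- d_star <- matrix(NA_real_, nrow(X), B,
                                               dimnames = list(rownames(X),
                                                               levels(bfac)))
  hyper <- vector("list", B)
  names(hyper) <- levels(bfac)
  iters <- integer(B)
  for (k in seq_len(B)) {
    Sb <- S[, cols[[k]], drop = FALSE]
    nbk <- length(cols[[k]])
    gh <- rowMeans(Sb)
    dh <- rowSums((Sb - gh)^2) / (nbk - 1)
    gh_f <- gh[eb_ok]; dh_f <- dh[eb_ok]
    g_bar <- mean(gh_f); t2 <- var(gh_f)
    mdh <- mean(dh_f); s2 <- var(dh_f)
    a_pr <- (2 * s2 + mdh^2) / s2
    b_pr <- (mdh * s2 + mdh^3) / s2
    degenerate <- !is.finite(t2) || t2 <= 1e-12 || !is.finite(s2) ||
      s2 <= 1e-12 || !is.finite(a_pr) || a_pr <= 1
    if (degenerate) {
      gs <- gh
      ds <- pmax(dh, 1e-12)
      iters[k] <- 0L
    } else {
      gs <- gh; ds <- dh
      for (it in seq_len(max_iter)) {
        g_new <- (t2 * nbk * gh + ds * g_bar) / (t2 * nbk + ds)
        sum2 <- rowSums((Sb - g_new)^2)
        d_new <- (0.5 * sum2 + b_pr) / (nbk / 2 + a_pr - 1)
        change <- max(abs(g_new - gs) / pmax(abs(gs), 1e-8),
                      abs(d_new - ds) / pmax(ds, 1e-8))
        gs <- g_new; ds <- d_new
        if (change < tol) break
      }
      iters[k] <- it
      ds <- pmax(ds, 1e-12)
    }
    g_hat[, k] <- gh; d_hat[, k] <- dh
    g_star[, k] <- gs; d_star[, k] <- ds
    hyper[[k]] <- c(gamma_bar = g_bar, tau2 = t2, a_prior = a_pr,
                    b_prior = b_pr)
  }

  structure(list(identity = FALSE,
                 probe_id = rownames(X),
                 batches = levels(bfac),
                 n_per_batch = as.integer(nb),
                 grand = grand,
                 var_pooled = var_pooled,
                 gamma_hat = g_hat, gamma_star = g_star,
                 delta_hat = d_hat, delta_star = d_star,
                 hyper = hyper,
                 zero_var = zero_var,
                 pure_batch = pure_batch,
                 iterations = iters,
                 tol = tol),
            class = "epi_combat")
}

#' Apply a fitted batch model to a beta table
#'
#' Adjusted value = grand mean + pooled SD * (standardised value - shrunken
#' batch location) / shrunken batch scale. Output is clipped to [0, 1];
#' the number of clipped cells is recorded in the `clipped` attribute.
#' Zero-variance probes pass through unchanged.
#'
#' @param beta Beta tibble compatible with the fitted model (same probes).
#' @param model An `epi_combat` from [fit_combat()].
#' @param sheet Sample sheet giving each sample's batch.
#' @param batch Name of the batch column.
#' @return The corrected beta tibble, with attribute `clipped`.
#' @export
apply_combat <- function(beta, model, sheet, batch = "batch") {
  stopifnot(inherits(model, "epi_combat"))
  if (model$identity) {
    out <- beta
    attr(out, "clipped") <- 0L
    return(out)
  }
  X <- beta_matrix(beta)
  if (!identical(rownames(X), model$probe_id)) {
    abort("beta probes do not match the fitted model")
  }
  bvec <- as.character(sheet[[batch]][match(colnames(X), sheet$sample_id)])
  if (anyNA(bvec) || !all(bvec %in% model$batches)) {
    abort("sample with unknown batch")
  }
  bi <- match(bvec, model$batches)
  eb_ok <- !model$zero_var & !model$pure_batch
  vp <- ifelse(eb_ok, model$var_pooled, 1)
  S <- (X - model$grand) / sqrt(vp)
  adj <- (S - model$gamma_star[, bi, drop = FALSE]) /
    sqrt(model$delta_star[, bi, drop = FALSE]) * sqrt(vp) + model$grand
  adj[model$zero_var, ] <- X[model$zero_var, ]
  adj[model$pure_batch, ] <- model$grand[model$pure_batch]
  clipped <- sum(adj < 0 | adj > 1, na.rm = TRUE)
  adj <- pmin(pmax(adj, 0), 1)
  out <- beta_tibble(adj)
  attr(out, "clipped") <- as.integer(clipped)
  out
}

#' Fit and apply batch correction in one step
#'
#' @inheritParams fit_combat
#' @return The corrected beta tibble (attributes `clipped` and `model`).
#' @export
correct_batch <- function(beta, sheet, batch = "batch", tol = 1e-4,
                          max_iter = 500) {
  model <- fit_combat(beta, sheet, batch = batch, tol = tol,
                      max_iter = max_iter)
  out <- apply_combat(beta, model, sheet, batch = batch)
  attr(out, "model") <- model
  out
}

#' @export
print.epi_combat <- function(x, ...) {
  if (x$identity) {
    cat("<epi_combat> identity model (single batch)\n")
  } else {
    cat("<epi_combat>", length(x$probe_id), "probes,",
        length(x$batches), "batches (",
        paste(x$batches, collapse = ", "), ")\n")
    cat("  fixed-point iterations per batch:",
        paste(x$iterations, collapse = ", "), "\n")
    cat("  zero-variance probes passed through:", sum(x$zero_var), "\n")
  }
  invisible(x)
}

#' @rdname fit_combat
#' @param x An `epi_combat` object.
#' @param ... Unused.
#' @method tidy epi_combat
#' @export
tidy.epi_combat <- function(x, ...) {
  if (x$identity) {
    return(tibble::tibble(probe_id = character(), batch = character(),
                          gamma_hat = numeric(), gamma_star = numeric(),
                          delta_hat = numeric(), delta_star = numeric()))
  }
  purrr::map_dfr(seq_along(x$batches), function(k) {
    tibble::tibble(probe_id = x$probe_id,
                   batch = x$batches[k],
                   gamma_hat = x$gamma_hat[, k],
                   gamma_star = x$gamma_star[, k],
                   delta_hat = x$delta_hat[, k],
                   delta_star = x$delta_star[, k])
  })
}

#' @rdname fit_combat
#' @method glance epi_combat
#' @export
glance.epi_combat <- function(x, ...) {
  if (x$identity) {
    return(tibble::tibble(n_probes = length(x$probe_id), n_batches = 1L,
                          identity = TRUE))
  }
  tibble::tibble(n_probes = length(x$probe_id),
                 n_batches = length(x$batches),
                 identity = FALSE,
                 n_zero_var = sum(x$zero_var),
                 max_iterations = max(x$iterations))
}
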