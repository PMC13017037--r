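#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills the missing cells of a scored trait table by iterated univariate
#' regressions: each incomplete column is regressed (ridge-stabilized
#' linear model with a Bayesian parameter draw) on all other columns at
#' their current values, and every missing cell receives the *observed*
#' value of a donor sampled uniformly from the `donors` rows whose
#' regression-predicted means are closest to the missing cell's prediction.
#' A sweep visits every incomplete column; `maxit` sweeps make one chain,
#' and `m` independent chains (each with its own random initial fill drawn
#' from the observed values) make the imputation set. Because donors are
#' observed values, every imputed cell is an element of its column's
#' observed support, and observed cells are never touched.
#'
#' @param table A trait table (tibble with an optional `subject_id` column;
#'   all other columns must be numeric). Every column must have at least
#'   `donors` observed values and at least one column must be complete.
#' @param m Number of imputed tables (default 5).
#' @param maxit Chained-equation sweeps per chain (default 50).
#' @param donors Size of the donor pool (default 5).
#' @param seed Integer seed.
#' @return An `imputation_set`: list with `completed_tables` (m complete
#'   tibbles), the settings, and the missing-cell mask.
#' @examples
#' tab <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' tab$b[1:3] <- NA
#' imp <- pmm_impute(tab, m = 2, maxit = 5, seed = 1)
#' length(imp$completed_tables)
#' @export
pmm_impute <- function(table, m = 5, maxit = 50, donors = 5, seed = NULL) {
  id_cols <- names(table)[!vapply(table, is.numeric, logical(1))]
  if (length(id_cols) > 1 ||
    (length(id_cols) == 1 && anyDuplicated(table[[id_cols]]))) {
    stop_traitnet(
      "pmm_impute: non-numeric columns other than a single id column"
    )
  }
  ids <- if (length(id_cols)) table[id_cols] else NULL
  num <- as.matrix(table[setdiff(names(table), id_cols)])
  if (!is.numeric(num)) {
    stop_traitnet("pmm_impute: all trait columns must be numeric")
  }
  n_obs_col <- colSums(!is.na(num))
  if (any(n_obs_col == 0)) {
    stop_traitnet(
      "pmm_impute: column(s) entirely missing: ",
      paste(colnames(num)[n_obs_col == 0], collapse = ", ")
    )
  }
  if (any(n_obs_col < donors)) {
    stop_traitnet(
      "pmm_impute: every column needs >= ", donors, " observed values"
    )
  }
  if (!any(n_obs_col == nrow(num))) {
    stop_traitnet("pmm_impute: need at least one fully observed column")
  }
  miss_mask <- is.na(num)
  incomplete <- which(colSums(miss_mask) > 0)

  completed <- lapply(seq_len(m), function(chain) {
    chain_seed <- derive_seed(seed, paste0("chain", chain))
    filled <- with_seed(chain_seed, {
      cur <- num
      # initial fill: random draws from each column's observed values
      for (j in incomplete) {
        obs <- num[!miss_mask[, j], j]
        cur[miss_mask[, j], j] <- sample(obs, sum(miss_mask[, j]),
          replace = TRUE
        )
      }
      for (it in seq_len(max(maxit, 1))) {
        for (j in incomplete) {
          cur[miss_mask[, j], j] <- pmm_draw(
            y = num[, j], x = cur[, -j, drop = FALSE],
            mis = miss_mask[, j], donors = donors
          )
        }
      }
      cur
    })
    out <- tibble::as_tibble(as.data.frame(filled))
    if (!is.null(ids)) out <- dplyr::bind_cols(ids, out)
    out[names(table)]
  })

  structure(
    list(
      completed_tables = completed,
      m = as.integer(m), maxit = as.integer(maxit),
      donors = as.integer(donors), seed = seed,
      missing_mask = miss_mask
    ),
    class = "imputation_set"
  )
}

# One PMM update of column y given predictors x: Bayesian regression draw,
# then donor matching on predicted means. Returns the imputed values for
# the missing rows. A small ridge keeps the normal equations well-posed on
# small cohorts with near-collinear traits.
pmm_draw <- function(y, x, mis, donors, ridge = 1e-5) {
  X <- cbind(1, x)
  Xo <- X[!mis, , drop = FALSE]
  yo <- y[!mis]
  S <- crossprod(Xo) + ridge * diag(ncol(Xo)) * mean(diag(crossprod(Xo)))
  beta_hat <- solve(S, crossprod(Xo, yo))
  resid <- yo - Xo %*% beta_hat
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(resid^2) / rchisq(1, df)
  cov_half <- chol(solve(S))
  beta_star <- beta_hat +
    sqrt(sigma2) * t(cov_half) %*% rnorm(ncol(Xo))
  pred_obs <- as.vector(Xo %*% beta_hat)
  pred_mis <- as.vector(X[mis, , drop = FALSE] %*% beta_star)
  vapply(pred_mis, function(p) {
    pool <- order(abs(pred_obs - p))[seq_len(donors)]
    yo[pool[sample.int(donors, 1)]]
  }, numeric(1))
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(
    "<imputation_set> m =", x$m, ", maxit =", x$maxit,
    ", donors =", x$donors, "\n"
  )
  cat("  missing cells imputed:", sum(x$missing_mask), "\n")
  invisible(x)
}

#' @export
tidy.imputation_set <- function(x, ...) {
  purrr::imap_dfr(
    x$completed_tables,
    function(tab, i) dplyr::mutate(tab, .imputation = i, .before = 1)
  )
}

#' Write an imputation set as suffixed tables plus a manifest
#'
#' @param imp An `imputation_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(imp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(imp$m)) {
    readr::write_tsv(
      imp$completed_tables[[i]],
      file.path(dir, sprintf("imputed_%02d.tsv", i))
    )
  }
  jsonlite::write_json(
    list(m = imp$m, maxit = imp$maxit, donors = imp$donors, seed = imp$seed),
    file.path(dir, "imputation_manifest.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
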