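#' Spearman correlation matrix of a trait table or imputation set
#'
#' All-pairs Spearman rank correlations (average-rank ties, pairwise
#' complete observations) with unadjusted t-approximation p-values. An
#' imputation set is pooled by Fisher-z averaging the per-table
#' correlations.
#'
#' @param x A trait table (tibble; non-numeric id columns are dropped) or
#'   an `imputation_set`.
#' @return A `correlation_matrix`: node names, `rho` matrix, `p_values`
#'   matrix, and the per-pair `n`.
#' @export
correlation_matrix <- function(x) {
  UseMethod("correlation_matrix")
}

#' @export
correlation_matrix.imputation_set <- function(x) {
  mats <- lapply(x$completed_tables, numeric_matrix)
  zs <- lapply(mats, function(m) {
    r <- spearman_rho(m)
    atanh(pmin(pmax(r, -0.999999), 0.999999))
  })
  z <- Reduce(`+`, zs) / length(zs)
  rho <- tanh(z)
  diag(rho) <- 1
  n_pair <- matrix(nrow(mats[[1]]), ncol(rho), ncol(rho))
  out <- new_correlation_matrix(rho, n_pair, colnames(mats[[1]]))
  out$pooled <- TRUE
  out$m <- x$m
  out
}

#' @export
correlation_matrix.default <- function(x) {
  m <- numeric_matrix(x)
  if (nrow(m) < 4) {
    stop_traitnet("correlation_matrix: need >= 4 subjects")
  }
  constant <- apply(m, 2, function(col) {
    sd(col, na.rm = TRUE) == 0 || all(is.na(col))
  })
  if (any(constant)) {
    warning(
      "correlation_matrix: constant column(s) set missing: ",
      paste(colnames(m)[constant], collapse = ", "),
      call. = FALSE
    )
  }
  rho <- spearman_rho(m)
  obs <- !is.na(m)
  n_pair <- crossprod(obs)
  new_correlation_matrix(rho, n_pair, colnames(m))
}

numeric_matrix <- function(x) {
  keep <- vapply(x, is.numeric, logical(1))
  as.matrix(x[keep])
}

spearman_rho <- function(m) {
  suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
}

new_correlation_matrix <- function(rho, n_pair, nodes) {
  dimnames(rho) <- list(nodes, nodes)
  tstat <- rho * sqrt((n_pair - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), pmax(n_pair - 2, 1))
  diag(p) <- NA
  structure(
    list(rho = rho, p_values = p, n = n_pair, nodes = nodes),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(
    "<correlation_matrix>", length(x$nodes), "nodes",
    if (isTRUE(x$pooled)) sprintf("(pooled over %d imputations)", x$m),
    "\n"
  )
  print(round(x$rho, 3))
  invisible(x)
}

#' @export
tidy.correlation_matrix <- function(x, ...) {
  ut <- upper.tri(x$rho)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    node_a = x$nodes[idx[, 1]],
    node_b = x$nodes[idx[, 2]],
    rho = x$rho[ut],
    p_value = x$p_values[ut],
    n = x$n[ut]
  )
}

#' Estimate the trait covariance network
#'
#' The `"ebicglasso"` estimator (default) runs the graphical lasso on the
#' Spearman correlation matrix over a log-spaced penalty path and selects
#' the model minimizing the extended BIC with hyperparameter `gamma`; edge
#' weights are the regularized partial correlations
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)`, i.e. associations between two
#' traits corrected for the influence of all the other nodes. The `"cor"`
#' estimator returns the marginal Spearman correlations as weights (the
#' correlation-matrix view of the network). A non-positive-semidefinite
#' input matrix is repaired by eigenvalue clipping (logged via a message).
#'
#' @param input A trait table, `imputation_set`, or `correlation_matrix`.
#' @param estimator `"ebicglasso"` or `"cor"`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Penalty grid size (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param n Sample size for the EBIC; taken from the input when it carries
#'   one.
#' @return A `trait_network` with the symmetric zero-diagonal weight
#'   matrix and estimator metadata.
#' @export
estimate_network <- function(input,
                             estimator = c("ebicglasso", "cor"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, n = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(input, "correlation_matrix")) {
    cm <- input
    n <- n %||% suppressWarnings(min(cm$n[upper.tri(cm$n)]))
  } else {
    if (is.null(n)) {
      n <- if (inherits(input, "imputation_set")) {
        nrow(input$completed_tables[[1]])
      } else {
        nrow(input)
      }
    }
    cm <- correlation_matrix(input)
  }
  S <- cm$rho
  nodes <- cm$nodes
  if (any(is.na(S))) {
    stop_traitnet(
      "estimate_network: correlation matrix has missing entries ",
      "(constant column?); cannot estimate"
    )
  }
  if (estimator == "cor") {
    w <- S
    diag(w) <- 0
    return(new_trait_network(w, nodes, "cor", n = n))
  }
  S <- repair_psd(S)
  p <- ncol(S)
  lambda_max <- max(abs(S[upper.tri(S)]), 0)
  if (lambda_max < 1e-12) {
    return(new_trait_network(
      matrix(0, p, p, dimnames = dimnames(S)), nodes,
      "ebicglasso",
      n = n, lambda = NA_real_, gamma = gamma
    ))
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
    length.out = n_lambda
  ))
  path <- glasso_path_cpp(S, lambdas)
  ebic <- -n * path$loglik + path$n_edges * log(n) +
    4 * gamma * path$n_edges * log(p)
  best <- which.min(ebic)
  theta <- path$theta[[best]]
  w <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(w) <- 0
  w[abs(w) < 1e-10] <- 0
  dimnames(w) <- dimnames(S)
  net <- new_trait_network(w, nodes, "ebicglasso",
    n = n, lambda = lambdas[best], gamma = gamma
  )
  net$ebic_path <- tibble::tibble(
    lambda = lambdas, ebic = ebic, n_edges = as.integer(path$n_edges)
  )
  net
}

new_trait_network <- function(weights, nodes, estimator, n = NULL,
                              lambda = NULL, gamma = NULL, mask = NULL) {
  dimnames(weights) <- list(nodes, nodes)
  structure(
    list(
      weights = weights, nodes = nodes, estimator = estimator,
      n = n, lambda = lambda, gamma = gamma, mask = mask
    ),
    class = "trait_network"
  )
}

# eigenvalue clipping to the PSD cone, rescaled back to unit diagonal
repair_psd <- function(S, floor_ev = 1e-6) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) >= -1e-10) { # numerically PSD: leave untouched
    return(S)
  }
  message(
    "repairing non-PSD correlation matrix (smallest eigenvalue ",
    format(min(ev$values), digits = 4), ")"
  )
  S2 <- ev$vectors %*% diag(pmax(ev$values, floor_ev)) %*% t(ev$vectors)
  S2 <- stats::cov2cor(S2)
  dimnames(S2) <- dimnames(S)
  S2
}

#' @export
print.trait_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(
    "<trait_network>", length(x$nodes), "nodes,", nz,
    "nonzero edges (", x$estimator, ")\n"
  )
  if (!is.null(x$lambda) && !is.na(x$lambda)) {
    cat("  penalty:", signif(x$lambda, 4), " gamma:", x$gamma, "\n")
  }
  if (!is.null(x$mask)) {
    cat("  significant edges:", sum(x$mask[upper.tri(x$mask)]), "\n")
  }
  invisible(x)
}

#' @export
tidy.trait_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble::tibble(
    node_a = x$nodes[idx[, 1]],
    node_b = x$nodes[idx[, 2]],
    weight = x$weights[ut]
  )
  if (!is.null(x$mask)) out$significant <- x$mask[ut]
  out
}

#' @export
glance.trait_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  tibble::tibble(
    nodes = length(x$nodes),
    n_edges = sum(x$weights[ut] != 0),
    n_significant = if (is.null(x$mask)) NA_integer_ else sum(x$mask[ut]),
    estimator = x$estimator,
    lambda = x$lambda %||% NA_real_,
    n = x$n %||% NA_integer_
  )
}

#' @export
autoplot.trait_network <- function(object, layout_radius = 1, ...) {
  p <- length(object$nodes)
  angle <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  pos <- tibble::tibble(
    node = object$nodes,
    x = layout_radius * cos(angle), y = layout_radius * sin(angle)
  )
  edges <- tidy(object) |>
    dplyr::filter(.data$weight != 0) |>
    dplyr::left_join(pos, by = c(node_a = "node")) |>
    dplyr::left_join(pos, by = c(node_b = "node"), suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_b, yend = .data$y_b,
        linewidth = abs(.data$weight), color = .data$weight > 0
      )
    ) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
      size = 8, color = "grey85"
    ) +
    ggplot2::geom_text(
      data = pos, ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
        label = .data$node
      ),
      size = 3
    ) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      guide = "none"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::theme_void()
}

#' Node centrality metrics of a trait network
#'
#' Strength (sum of absolute incident edge weights), one-step expected
#' influence (signed sum of incident weights, separating positive from
#' negative connections), and eigenvector centrality (principal
#' eigenvector of the absolute weight matrix, scaled to a maximum of 1).
#' An empty network has zero strength and expected influence everywhere;
#' its eigenvector centrality is undefined and reported as 0 with a
#' warning.
#'
#' @param network A `trait_network`.
#' @return A tibble: `node`, `strength`, `expected_influence`,
#'   `eigenvector`.
#' @export
centrality <- function(network) {
  if (!inherits(network, "trait_network")) {
    stop_traitnet("centrality: need a trait_network")
  }
  w <- network$weights
  aw <- abs(w)
  strength <- rowSums(aw)
  ei <- rowSums(w)
  if (all(aw == 0)) {
    warning(
      "centrality: empty network; eigenvector centrality undefined, set 0",
      call. = FALSE
    )
    eig <- rep(0, length(strength))
  } else {
    es <- eigen(aw, symmetric = TRUE)
    v <- abs(es$vectors[, which.max(es$values)])
    eig <- v / max(v)
  }
  tibble::tibble(
    node = network$nodes,
    strength = unname(strength),
    expected_influence = unname(ei),
    eigenvector = unname(eig)
  )
}

#' Plot centrality profiles
#'
#' @param cent A [centrality()] tibble.
#' @return A ggplot with one panel per metric.
#' @export
plot_centrality <- function(cent) {
  cent |>
    tidyr::pivot_longer(-"node", names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$value, y = .data$node, group = .data$metric
    )) +
    ggplot2::geom_point() +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Nonparametric edge-weight bootstrap and the significance mask
#'
#' Resamples subjects (rows) with replacement, re-estimates the network on
#' every resample, and summarizes each edge with its bootstrap mean,
#' percentile confidence interval and sign-agreement fraction. Edges whose
#' interval excludes zero form the significance mask — the unweighted view
#' of the network. A resample in which some trait is constant leaves that
#' trait's edges missing for that resample; such resamples are excluded
#' from the affected edges' interval denominators.
#'
#' @param table A trait table (complete, or with missing cells handled by
#'   pairwise Spearman).
#' @param estimator,... Passed to [estimate_network()].
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param ci_level Interval coverage (default 0.95).
#' @return An `edge_stability` object: per-edge tibble, the full-sample
#'   network with the mask attached, and the bootstrap draws.
#' @export
edge_bootstrap <- function(table, estimator = "ebicglasso", n_boot = 1000,
                           seed = NULL, ci_level = 0.95, ...) {
  m <- numeric_matrix(table)
  n <- nrow(m)
  if (n < 8) {
    stop_traitnet("edge_bootstrap: need >= 8 subjects")
  }
  full <- estimate_network(table, estimator = estimator, n = n, ...)
  p <- length(full$nodes)
  ut <- upper.tri(full$weights)
  n_edges <- sum(ut)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_edges, n_boot)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      w <- boot_network_weights(m, estimator, ...)
      if (is.null(w)) {
        dropped <- dropped + 1L
        next
      }
      out[, b] <- w[ut]
    }
    attr(out, "dropped") <- dropped
    out
  })
  if (attr(draws, "dropped") > 0) {
    message(
      attr(draws, "dropped"),
      " resample(s) left edges missing (constant trait in resample)"
    )
  }
  alpha <- (1 - ci_level) / 2
  idx <- which(ut, arr.ind = TRUE)
  full_w <- full$weights[ut]
  edges <- tibble::tibble(
    node_a = full$nodes[idx[, 1]],
    node_b = full$nodes[idx[, 2]],
    weight = full_w,
    boot_mean = apply(draws, 1, mean, na.rm = TRUE),
    ci_low = apply(draws, 1, quantile, probs = alpha, na.rm = TRUE),
    ci_high = apply(draws, 1, quantile, probs = 1 - alpha, na.rm = TRUE),
    n_used = apply(draws, 1, function(x) sum(!is.na(x)))
  )
  edges$sign_agreement <- vapply(seq_len(n_edges), function(e) {
    d <- draws[e, !is.na(draws[e, ])]
    if (!length(d)) {
      return(NA_real_)
    }
    mean(sign(d) == sign(full_w[e]))
  }, numeric(1))
  edges$significant <- edges$ci_low > 0 | edges$ci_high < 0
  mask <- matrix(FALSE, p, p, dimnames = dimnames(full$weights))
  mask[ut] <- edges$significant
  mask <- mask | t(mask)
  full$mask <- mask
  structure(
    list(
      edges = edges, network = full, draws = draws,
      n_boot = n_boot, seed = seed, ci_level = ci_level
    ),
    class = "edge_stability"
  )
}

# weights of one bootstrap resample; NULL if the network cannot be
# estimated at all, a weight matrix with NA rows/cols for constant traits
# otherwise
boot_network_weights <- function(m, estimator, ...) {
  idx <- sample.int(nrow(m), replace = TRUE)
  sub <- m[idx, , drop = FALSE]
  const <- apply(sub, 2, function(col) sd(col, na.rm = TRUE) == 0)
  const[is.na(const)] <- TRUE
  if (all(const)) {
    return(NULL)
  }
  sub_tab <- tibble::as_tibble(as.data.frame(sub))
  if (!any(const)) {
    # PSD repairs inside resamples are routine; keep the log quiet
    net <- suppressMessages(estimate_network(sub_tab,
      estimator = estimator, n = nrow(sub), ...
    ))
    return(net$weights)
  }
  keep <- !const
  net <- tryCatch(
    suppressMessages(estimate_network(sub_tab[, keep, drop = FALSE],
      estimator = estimator, n = nrow(sub), ...
    )),
    error = function(e) NULL
  )
  if (is.null(net)) {
    return(NULL)
  }
  w <- matrix(NA_real_, ncol(m), ncol(m), dimnames = list(
    colnames(m), colnames(m)
  ))
  w[keep, keep] <- net$weights
  w
}

#' @export
print.edge_stability <- function(x, ...) {
  cat(
    "<edge_stability>", nrow(x$edges), "edges,", x$n_boot,
    "bootstrap resamples\n"
  )
  cat("  significant (CI excludes 0):", sum(x$edges$significant), "\n")
  invisible(x)
}

#' @export
tidy.edge_stability <- function(x, ...) {
  x$edges
}

#' @export
autoplot.edge_stability <- function(object, ...) {
  object$edges |>
    dplyr::mutate(
      edge = paste(.data$node_a, .data$node_b, sep = "--"),
      edge = stats::reorder(.data$edge, .data$weight)
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$weight, y = .data$edge)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0, color = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant)) +
    ggplot2::labs(x = "edge weight (bootstrap 95% CI)", y = NULL)
}

#' Case-dropping subset bootstrap and the CS-coefficient
#'
#' For each proportion in `drop_grid`, repeatedly drops that share of
#' subjects (subsampling without replacement), re-estimates the network
#' and its centralities, and correlates each subset centrality vector with
#' the full-sample one. The CS-coefficient of a metric is the largest drop
#' proportion at which at least `certainty` of the subsets still correlate
#' at `r_threshold` or better (0 if none does); values below 0.25 are
#' flagged unreliable.
#'
#' @param table A trait table.
#' @param metrics Centrality metrics to assess (default all three).
#' @param estimator,... Passed to [estimate_network()].
#' @param drop_grid Drop proportions (default 0.05 to 0.75 by 0.05);
#'   proportions leaving fewer than 4 subjects are removed with a warning.
#' @param n_boot Subsets per proportion (default 1000).
#' @param r_threshold Required correlation with the full sample (default
#'   0.7).
#' @param certainty Required fraction of subsets at or above the threshold
#'   (default 0.95).
#' @param seed Integer seed.
#' @return A `cs_result`: per-metric CS summary, the per-proportion detail
#'   table, and the raw subset correlations.
#' @export
cs_coefficient <- function(table,
                           metrics = c(
                             "strength", "eigenvector",
                             "expected_influence"
                           ),
                           estimator = "ebicglasso",
                           drop_grid = seq(0.05, 0.75, by = 0.05),
                           n_boot = 1000, r_threshold = 0.7,
                           certainty = 0.95, seed = NULL, ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  m <- numeric_matrix(table)
  n <- nrow(m)
  keep_sizes <- pmax(round(n * (1 - drop_grid)), 0)
  usable <- keep_sizes >= 4
  if (!all(usable)) {
    warning(
      "dropping grid proportions leaving < 4 subjects: ",
      paste(drop_grid[!usable], collapse = ", "),
      call. = FALSE
    )
    drop_grid <- drop_grid[usable]
    keep_sizes <- keep_sizes[usable]
  }
  full <- estimate_network(table, estimator = estimator, n = n, ...)
  cent0 <- centrality(full)
  cors <- with_seed(seed, {
    arr <- array(
      NA_real_, c(length(drop_grid), n_boot, length(metrics)),
      dimnames = list(NULL, NULL, metrics)
    )
    for (g in seq_along(drop_grid)) {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, keep_sizes[g])
        sub <- tibble::as_tibble(as.data.frame(m[idx, , drop = FALSE]))
        cent_sub <- tryCatch(
          suppressWarnings(suppressMessages(centrality(estimate_network(
            sub,
            estimator = estimator, n = keep_sizes[g], ...
          )))),
          error = function(e) NULL
        )
        if (is.null(cent_sub)) next
        for (met in metrics) {
          arr[g, b, met] <- suppressWarnings(
            cor(cent0[[met]], cent_sub[[met]])
          )
        }
      }
    }
    arr
  })
  build_cs_result(cors, drop_grid, metrics, n_boot, r_threshold,
    certainty,
    seed = seed
  )
}

build_cs_result <- function(cors, drop_grid, metrics, n_boot,
                            r_threshold, certainty, seed = NULL) {
  detail <- purrr::map_dfr(metrics, function(met) {
    cm <- matrix(cors[, , met], nrow = length(drop_grid))
    tibble::tibble(
      metric = met,
      drop_prop = drop_grid,
      # undefined subset centralities (NA correlations) count as failures
      fraction_ok = rowMeans(!is.na(cm) & cm >= r_threshold),
      mean_cor = rowMeans(cm, na.rm = TRUE)
    )
  })
  summary <- detail |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      cs_coefficient = {
        ok <- .data$drop_prop[.data$fraction_ok >= certainty]
        if (length(ok)) max(ok) else 0
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(reliable = .data$cs_coefficient >= 0.25)
  structure(
    list(
      summary = summary, detail = detail, cors = cors,
      drop_grid = drop_grid, n_boot = n_boot,
      r_threshold = r_threshold, certainty = certainty, seed = seed
    ),
    class = "cs_result"
  )
}

#' Recompute a CS-coefficient at a different correlation threshold
#'
#' Reuses the stored subset correlations of a [cs_coefficient()] run, so
#' the comparison across thresholds is on identical resamples.
#'
#' @param x A `cs_result`.
#' @param r_threshold New correlation threshold.
#' @return A new `cs_result`.
#' @export
cs_rethreshold <- function(x, r_threshold) {
  build_cs_result(
    x$cors, x$drop_grid, dimnames(x$cors)[[3]], x$n_boot,
    r_threshold, x$certainty,
    seed = x$seed
  )
}

#' @export
print.cs_result <- function(x, ...) {
  cat(
    "<cs_result> r >=", x$r_threshold, "with", x$certainty,
    "certainty;", x$n_boot, "subsets per proportion\n"
  )
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cs_result <- function(x, ...) {
  x$detail
}

#' @export
glance.cs_result <- function(x, ...) {
  x$summary
}

#' @export
autoplot.cs_result <- function(object, ...) {
  object$detail |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$drop_prop, y = .data$fraction_ok, color = .data$metric
    )) +
    ggplot2::geom_hline(
      yintercept = object$certainty, linetype = 2, color = "grey60"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "proportion of subjects dropped",
      y = sprintf("fraction of subsets with r >= %.2f", object$r_threshold)
    )
}
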