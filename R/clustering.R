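## squared Euclidean distances between rows of X and rows of C
dist2 <- function(X, C) {
  outer(rowSums(X ^ 2), rowSums(C ^ 2), "+") - 2 * X %*% t(C)
}

## Greedy k-means++ seeding: each new center is the best of a few candidates
## sampled proportionally to squared distance, so a single run covers
## well-separated groups with high probability.
kpp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    trials <- 2L + floor(log(k))
    d2min <- rowSums((X - rep(X[idx[1], ], each = n)) ^ 2)
    for (j in 2:k) {
      tot <- sum(d2min)
      cand <- if (tot <= 0) sample.int(n, trials, replace = TRUE) else
        sample.int(n, trials, replace = TRUE, prob = d2min / tot)
      best <- NULL; best_pot <- Inf
      for (c in cand) {
        pot <- sum(pmin(d2min, rowSums((X - rep(X[c, ], each = n)) ^ 2)))
        if (pot < best_pot) { best_pot <- pot; best <- c }
      }
      idx[j] <- best
      d2min <- pmin(d2min, rowSums((X - rep(X[best, ], each = n)) ^ 2))
    }
  }
  idx
}

lloyd_once <- function(X, k, max_iter, init_idx) {
  n <- nrow(X)
  centers <- X[init_idx, , drop = FALSE]
  assign_old <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    ## re-seed empty clusters from the point farthest from its center
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) == 0L) break
      cur <- d2[cbind(seq_len(n), assign)]
      far <- which.max(cur)
      centers[empty[1], ] <- X[far, ]
      assign[far] <- empty[1]
      d2[, empty[1]] <- rowSums((X - rep(X[far, ], each = n)) ^ 2)
    }
    counts <- tabulate(assign, k)
    centers <- rowsum(X, assign, reorder = TRUE) / counts
    if (identical(assign, assign_old)) break
    assign_old <- assign
  }
  wss <- sum((X - centers[assign, , drop = FALSE]) ^ 2)
  list(assign = assign, centers = centers, within_ss = wss)
}

#' Euclidean k-means of expression profiles
#'
#' Lloyd's algorithm with Euclidean distance, optional row mean-centering,
#' re-seeding of empty clusters from the farthest point, and the best of
#' `n_init` random restarts by within-cluster sum of squares. Missing
#' values are mean-imputed per gene (logged in an attribute).
#'
#' @param profiles numeric genes x conditions matrix (e.g. per-comparison
#'   log2 fold changes of differential genes).
#' @param k number of clusters.
#' @param max_iter Lloyd iteration cap (default 100).
#' @param n_init random restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @param center_rows subtract each row's mean first (default TRUE).
#' @return object of class `cluster_model`: `k`, `assignments` (named by
#'   rownames), `centroids`, `within_ss`.
#' @export
km_fit <- function(profiles, k, max_iter = 100L, n_init = 10L, seed = 1L,
                   center_rows = TRUE) {
  X <- prepare_profiles(profiles, center_rows)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(X)) stop("k exceeds the number of genes", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd_once(X, k, max_iter, kpp_init(X, k))
    if (is.null(best) || fit$within_ss < best$within_ss) best <- fit
  }
  structure(list(k = k,
                 assignments = stats::setNames(best$assign, rownames(X)),
                 centroids = best$centers, within_ss = best$within_ss,
                 n_imputed = attr(X, "n_imputed")),
            class = "cluster_model")
}

prepare_profiles <- function(profiles, center_rows) {
  X <- as.matrix(profiles)
  n_imp <- sum(is.na(X))
  if (n_imp > 0L) {
    for (i in which(rowSums(is.na(X)) > 0L)) {
      m <- mean(X[i, ], na.rm = TRUE)
      X[i, is.na(X[i, ])] <- if (is.finite(m)) m else 0
    }
    message(sprintf("mean-imputed %d missing profile values", n_imp))
  }
  if (center_rows) X <- X - rowMeans(X)
  attr(X, "n_imputed") <- n_imp
  X
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, within-SS = %.4g, sizes: %s\n",
              x$k, x$within_ss,
              paste(tabulate(x$assignments, x$k), collapse = " ")))
  if (!is.null(x$selected_k))
    cat(sprintf("  selected k = %d by the <%g%% gain-of-power rule\n",
                x$selected_k, x$gain_threshold))
  invisible(x)
}

#' Adjusted Figure of Merit for a candidate cluster number
#'
#' Leave-one-condition-out predictive-power estimate of a k-means
#' clustering: for each condition, the remaining conditions are clustered
#' and the root-mean-square deviation of the left-out condition from its
#' cluster means is computed; these are averaged over conditions, scaled
#' by the adjustment factor `sqrt(n / (n - k))` (n = number of genes)
#' that corrects the natural decrease with k, and averaged over `n_runs`
#' random initializations. Lower is better.
#'
#' @inheritParams km_fit
#' @param n_runs random initializations averaged over (default 50).
#' @param adjust apply the `sqrt(n / (n - k))` factor (default TRUE).
#' @return the adjusted FOM value.
#' @export
figure_of_merit <- function(profiles, k, n_runs = 50L, seed = 1L,
                            max_iter = 100L, center_rows = TRUE,
                            adjust = TRUE) {
  X <- prepare_profiles(profiles, center_rows)
  n <- nrow(X); m <- ncol(X)
  if (m < 2L) stop("FOM needs >= 2 conditions", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of genes", call. = FALSE)
  set.seed(seed)
  total <- 0
  for (r in seq_len(n_runs)) {
    per_run <- 0
    for (e in seq_len(m)) {
      fit <- lloyd_once(X[, -e, drop = FALSE], k, max_iter,
                        kpp_init(X[, -e, drop = FALSE], k))
      mu <- rowsum(X[, e], fit$assign) / tabulate(fit$assign, k)
      per_run <- per_run + sqrt(mean((X[, e] - mu[fit$assign]) ^ 2))
    }
    total <- total + per_run / m
  }
  fom <- total / n_runs
  if (adjust) fom <- fom * sqrt(n / (n - k))
  fom
}

#' Percent gain of predictive power between consecutive cluster numbers
#'
#' `gain(k+1) = ((FOM(k) - FOM(k+1)) / FOM(k)) * 100`, attributed to the
#' larger k of each consecutive pair. A zero FOM leaves the gain undefined
#' (NA).
#'
#' @param fom_curve numeric vector of FOM values named by contiguous k.
#' @return named numeric vector of gains for each k after the first.
#' @export
gain_of_power <- function(fom_curve) {
  ks <- as.integer(names(fom_curve))
  if (length(fom_curve) < 2L || is.null(names(fom_curve)) ||
      any(diff(ks) != 1L))
    stop("fom_curve must be named by >= 2 consecutive k values", call. = FALSE)
  prev <- fom_curve[-length(fom_curve)]
  nxt <- fom_curve[-1]
  gain <- ifelse(prev == 0, NA_real_, (prev - nxt) / prev * 100)
  stats::setNames(as.numeric(gain), ks[-1])
}

#' Select the cluster number by the gain-of-power rule
#'
#' The smallest k whose gain of predictive power falls below
#' `threshold_percent` (default 1\%); if no k qualifies, the largest k
#' examined is returned with a warning.
#'
#' @param gain_curve named vector from [gain_of_power()].
#' @param threshold_percent stopping threshold (default 1).
#' @return the selected k.
#' @export
select_k <- function(gain_curve, threshold_percent = 1.0) {
  if (length(gain_curve) == 0L) stop("empty gain curve", call. = FALSE)
  ks <- as.integer(names(gain_curve))
  hit <- which(!is.na(gain_curve) & gain_curve < threshold_percent)
  if (length(hit) == 0L) {
    warning("no k reached the gain threshold; returning the largest k examined")
    return(max(ks))
  }
  ks[hit[1]]
}

#' Cluster fold-change profiles with FOM-based choice of k
#'
#' Full clustering stage: computes the adjusted FOM curve from k = 1
#' upward, stops at the first k whose gain of power drops below the
#' threshold (or at `k_max`), then fits the final k-means at the selected
#' k with `n_init` restarts.
#'
#' @inheritParams km_fit
#' @inheritParams figure_of_merit
#' @param k_max largest cluster number examined (default 50).
#' @param threshold_percent gain-of-power stopping threshold (default 1).
#' @return a `cluster_model` additionally carrying `fom_curve`,
#'   `gain_curve`, `selected_k` and `gain_threshold`.
#' @export
cluster_profiles <- function(profiles, k_max = 50L, threshold_percent = 1.0,
                             n_runs = 50L, n_init = 10L, max_iter = 100L,
                             seed = 1L, center_rows = TRUE, adjust = TRUE) {
  X <- prepare_profiles(profiles, center_rows)
  k_max <- min(k_max, nrow(X) - 1L)
  fom <- numeric(0)
  selected <- NA_integer_
  for (k in seq_len(k_max)) {
    fom[as.character(k)] <- figure_of_merit(X, k, n_runs = n_runs,
                                            seed = stage_seed(seed, paste0("fom", k)),
                                            max_iter = max_iter,
                                            center_rows = FALSE, adjust = adjust)
    if (k >= 2L) {
      gain <- gain_of_power(fom)
      last <- gain[length(gain)]
      if (!is.na(last) && last < threshold_percent) { selected <- k; break }
    }
  }
  gain <- gain_of_power(fom)
  if (is.na(selected)) {
    warning("no k reached the gain threshold before k_max; using k_max")
    selected <- as.integer(names(fom)[length(fom)])
  }
  model <- km_fit(X, selected, max_iter = max_iter, n_init = n_init,
                  seed = stage_seed(seed, "kmeans"), center_rows = FALSE)
  model$fom_curve <- fom
  model$gain_curve <- gain
  model$selected_k <- selected
  model$gain_threshold <- threshold_percent
  model
}
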