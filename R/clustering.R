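# internal: extract the n x 5 share matrix (and ids) from a shares table
shares_matrix <- function(shares, check_sum = TRUE) {
  cols <- tolower(cnl_colours())
  if (is.matrix(shares)) {
    stopifnot(ncol(shares) == 5)
    colnames(shares) <- cols
    ids <- seq_len(nrow(shares))
    m <- shares
  } else {
    stopifnot(all(cols %in% names(shares)))
    ids <- shares$person_id %||% seq_len(nrow(shares))
    m <- as.matrix(shares[, cols])
  }
  if (check_sum && any(abs(rowSums(m) - 100) > 1e-6)) {
    stop("colour shares must sum to 100 per row")
  }
  list(m = m, ids = ids)
}

# internal: total within-cluster sum of squares of a labelled partition
partition_wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(scale(xs, center = TRUE, scale = FALSE)^2)
  }, numeric(1)))
}

#' Cluster individuals by their colour energy shares
#'
#' Two-stage partitioning in the style of the classic SAS workflow: Ward
#' hierarchical clustering (on a subsample when `n` exceeds
#' `config$clustering$hier_subsample`) seeds `k` centroids, which are then
#' refined by Lloyd k-means on the full data until assignments stabilise
#' (at most `config$clustering$kmeans_iter` iterations). Deterministic
#' given `seed`.
#'
#' @param shares Tibble with `person_id` and `green`..`red` columns (rows
#'   summing to 100), or a bare n x 5 matrix.
#' @param k Number of clusters (>= 1, < n).
#' @param seed Integer seed governing the hierarchical subsample.
#' @param config A [cnl_config()] list.
#' @return A list of class `cnl_clusters`: `k`, `centroids` (k x 5 tibble),
#'   `assignments` (tibble person_id, cluster), `withinss`, `totss`,
#'   `r_squared`, `seed`.
#' @export
fit_clusters <- function(shares, k, seed = 1L, config = cnl_config()) {
  sm <- shares_matrix(shares)
  x <- sm$m
  n <- nrow(x)
  k <- as.integer(k)
  if (n <= k) stop("need more observations than clusters (n = ", n,
                   ", k = ", k, ")")
  if (config$clustering$standardize) x <- scale(x)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct share profiles; fitting k = ",
            n_distinct, " instead of ", k)
    k <- n_distinct
  }
  set.seed(seed)
  sub_n <- min(n, config$clustering$hier_subsample)
  idx <- if (sub_n < n) sort(sample.int(n, sub_n)) else seq_len(n)
  if (k == 1L) {
    centers <- matrix(colMeans(x), nrow = 1,
                      dimnames = list(NULL, colnames(x)))
    assign <- rep(1L, n)
    wss <- sum(scale(x, center = TRUE, scale = FALSE)^2)
  } else {
    hc <- stats::hclust(stats::dist(x[idx, , drop = FALSE]),
                        method = "ward.D2")
    seed_labels <- stats::cutree(hc, k = k)
    centers <- do.call(rbind, lapply(split(idx, seed_labels), function(i) {
      colMeans(x[i, , drop = FALSE])
    }))
    centers <- unique(centers)
    if (nrow(centers) < k) {
      warning("degenerate seeding collapsed to ", nrow(centers), " clusters")
      k <- nrow(centers)
    }
    km <- stats::kmeans(x, centers = centers,
                        iter.max = config$clustering$kmeans_iter,
                        algorithm = "Lloyd")
    assign <- km$cluster
    wss <- km$tot.withinss
  }
  totss <- sum(scale(x, center = TRUE, scale = FALSE)^2)
  centroids <- do.call(rbind, lapply(split(seq_len(n), assign), function(i) {
    colMeans(sm$m[i, , drop = FALSE])
  }))
  structure(list(
    k = k,
    centroids = tibble::as_tibble(centroids),
    assignments = tibble::tibble(person_id = sm$ids,
                                 cluster = as.integer(assign)),
    withinss = wss,
    totss = totss,
    r_squared = if (totss > 0) 1 - wss / totss else NA_real_,
    seed = seed
  ), class = "cnl_clusters")
}

# internal: SAS-style cubic clustering criterion for a partition with
# R-squared r2 and q clusters of the (uncentered) data matrix x.
ccc_criterion <- function(x, r2, q) {
  n <- nrow(x)
  p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- sqrt(pmax(eigen(crossprod(xc) / (n - 1), symmetric = TRUE,
                       only.values = TRUE)$values, 0))
  # hyperbox dimensionality p*: largest j with s_j >= c, c the geometric
  # mean edge implied by q clusters
  pstar <- 1L
  cval <- s[1] / q
  for (j in rev(seq_len(p))) {
    if (s[j] <= 0) next
    cj <- (prod(s[1:j]) / q)^(1 / j)
    if (s[j] >= cj) {
      pstar <- j
      cval <- cj
      break
    }
  }
  u <- s / cval
  top <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < p) {
    jj <- (pstar + 1L):p
    top <- top + sum(u[jj]^2 / (n + u[jj]))
  }
  e_r2 <- 1 - (top / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  log((1 - e_r2) / (1 - r2)) * sqrt(n * pstar / 2) / ((0.001 + e_r2)^1.2)
}

#' Cluster-count diagnostics from the Ward merge sequence
#'
#' For each candidate `k`, cuts the Ward tree and reports `r2`
#' (1 - WSS/TSS), the semi-partial R-squared (`spr2`, the R-squared lost
#' when merging from `k` to `k - 1`), the pseudo-T-squared of the merge
#' undone at `k`, and the cubic clustering criterion (`ccc`). The
#' suggested `k` is the first local CCC peak (with CCC > 2) agreeing with
#' the semi-partial-R-squared elbow; `NA` when no peak clears the
#' structure threshold, as for unclustered data.
#'
#' @inheritParams fit_clusters
#' @param k_range Integer vector of candidate cluster counts (>= 2).
#' @return A list of class `cnl_diagnostics`: `table` (one row per k) and
#'   `suggested_k`.
#' @export
cluster_diagnostics <- function(shares, k_range = 2:6, seed = 1L,
                                config = cnl_config()) {
  sm <- shares_matrix(shares)
  x <- sm$m
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1 || min(k_range) < 2 || max(k_range) >= n) {
    stop("k_range must lie within [2, n)")
  }
  if (config$clustering$standardize) x <- scale(x)
  set.seed(seed)
  sub_n <- min(n, config$clustering$hier_subsample)
  idx <- if (sub_n < n) sort(sample.int(n, sub_n)) else seq_len(n)
  xs <- x[idx, , drop = FALSE]
  hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
  totss <- sum(scale(xs, center = TRUE, scale = FALSE)^2)
  ks <- sort(unique(c(k_range, k_range - 1L, k_range + 1L)))
  ks <- ks[ks >= 1 & ks < nrow(xs)]
  cuts <- stats::cutree(hc, k = ks)  # matrix, one column per k
  colnames(cuts) <- as.character(ks)
  r2_of <- vapply(as.character(ks), function(kc) {
    1 - partition_wss(xs, cuts[, kc]) / totss
  }, numeric(1))

  pseudo_t2 <- function(k) {
    if (!as.character(k + 1) %in% colnames(cuts)) return(NA_real_)
    lk <- cuts[, as.character(k)]
    lk1 <- cuts[, as.character(k + 1)]
    # the cluster at level k that holds two clusters of level k+1
    tab <- table(lk, lk1)
    merged <- which(rowSums(tab > 0) == 2)
    if (!length(merged)) return(NA_real_)
    m <- as.integer(rownames(tab)[merged[1]])
    parts <- as.integer(colnames(tab)[tab[merged[1], ] > 0])
    i_m <- which(lk == m)
    w_m <- partition_wss(xs[i_m, , drop = FALSE], rep(1, length(i_m)))
    w_kl <- sum(vapply(parts, function(p) {
      i <- which(lk1 == p)
      partition_wss(xs[i, , drop = FALSE], rep(1, length(i)))
    }, numeric(1)))
    df <- length(i_m) - 2
    if (df <= 0 || w_kl <= 0) return(Inf)
    (w_m - w_kl) / (w_kl / df)
  }

  tab <- tibble::tibble(
    k = k_range,
    r2 = r2_of[as.character(k_range)],
    spr2 = r2_of[as.character(k_range)] -
      ifelse(k_range - 1 >= 1, r2_of[as.character(k_range - 1)], 0),
    pseudo_t2 = vapply(k_range, pseudo_t2, numeric(1)),
    ccc = vapply(seq_along(k_range), function(i) {
      ccc_criterion(xs, r2_of[as.character(k_range[i])], k_range[i])
    }, numeric(1))
  )
  structure(list(table = tab, suggested_k = suggest_k(tab)),
            class = "cnl_diagnostics")
}

# internal: selection rule — first local CCC peak (a k whose CCC exceeds
# both neighbours; the first k qualifies when CCC then falls) agreeing
# with the semi-partial-R2 elbow, falling back to the first peak. NA when
# CCC has no peak over the range — e.g. monotone CCC on unclustered data.
suggest_k <- function(tab) {
  m <- nrow(tab)
  if (m == 0) return(NA_integer_)
  if (m == 1) return(as.integer(tab$k[1]))
  is_peak <- vapply(seq_len(m), function(i) {
    left_ok <- i == 1 || tab$ccc[i] > tab$ccc[i - 1]
    right_ok <- i < m && tab$ccc[i] > tab$ccc[i + 1]
    left_ok && right_ok
  }, logical(1))
  candidates <- tab$k[is_peak]
  if (!length(candidates)) return(NA_integer_)
  drop_after <- tab$spr2 - c(tab$spr2[-1], NA)
  elbow_k <- tab$k[which.max(drop_after)]
  if (length(elbow_k) && any(candidates == elbow_k)) {
    return(as.integer(min(candidates[candidates == elbow_k])))
  }
  as.integer(candidates[1])
}

#' Name dietary-profile clusters by their colour signature
#'
#' Rule-based labelling of fitted clusters: the cluster with the highest
#' Green share is `Healthy`; among the rest the highest Pink share is
#' `Western`; among the rest the highest Yellow share is `Traditional`;
#' any remaining clusters are `Other1`, `Other2`, ... in cluster order.
#' Ties break towards the lower cluster index (reported via a message).
#'
#' @param model A `cnl_clusters` fit.
#' @return Named character vector: cluster index -> profile label.
#' @export
label_profiles <- function(model) {
  stopifnot(inherits(model, "cnl_clusters"))
  cent <- model$centroids
  k <- nrow(cent)
  labels <- rep(NA_character_, k)
  pick <- function(colour, remaining) {
    v <- cent[[colour]][remaining]
    best <- which(v == max(v))
    if (length(best) > 1) message("tie on ", colour,
                                  " broken by cluster index")
    remaining[min(best)]
  }
  remaining <- seq_len(k)
  for (rule in list(c("green", "Healthy"), c("pink", "Western"),
                    c("yellow", "Traditional"))) {
    if (!length(remaining)) break
    i <- pick(rule[1], remaining)
    labels[i] <- rule[2]
    remaining <- setdiff(remaining, i)
  }
  if (length(remaining)) {
    labels[remaining] <- paste0("Other", seq_along(remaining))
  }
  stats::setNames(labels, seq_len(k))
}

#' @export
print.cnl_clusters <- function(x, ...) {
  cat("5-CNL dietary-profile clustering: k =", x$k,
      sprintf("(R² = %.3f)\n", x$r_squared))
  print(dplyr::count(x$assignments, .data$cluster))
  print(round(as.data.frame(x$centroids), 1))
  invisible(x)
}

#' @export
print.cnl_diagnostics <- function(x, ...) {
  print(as.data.frame(x$table), digits = 4)
  cat("suggested k:", x$suggested_k, "\n")
  invisible(x)
}
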