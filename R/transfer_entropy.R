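#' Discrete plug-in transfer entropy (bits)
#'
#' Plug-in estimator of the transfer entropy from a source state series X
#' to a target series Y with history length k:
#' \deqn{TE(X \to Y) = \sum p(y_{t+1}, y_t^{(k)}, x_t^{(k)})
#'   \log_2 \frac{p(y_{t+1} | y_t^{(k)}, x_t^{(k)})}
#'               {p(y_{t+1} | y_t^{(k)})}}
#' with probabilities replaced by empirical frequencies over all valid t.
#' The estimate is nonnegative, zero exactly when Y's next state is
#' conditionally independent of (or deterministic given) its own k-history,
#' and invariant to relabeling of the state alphabets.
#'
#' @param x source series (finite discrete states).
#' @param y target series, same length.
#' @param k history length in bins (>= 1).
#' @return transfer entropy in bits.
#' @export
discrete_te <- function(x, y, k = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= k + 1) stop("series length must be >= k + 2")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("states must be finite and non-missing")
  # relabel states to 0 .. a-1 (estimate is invariant to the labels)
  xl <- match(x, sort(unique(x))) - 1L
  yl <- match(y, sort(unique(y))) - 1L
  ax <- max(xl) + 1L
  ay <- max(yl) + 1L
  n_t <- n - k
  # history codes: most recent state in the lowest digit
  yh <- integer(n_t)
  xh <- integer(n_t)
  for (j in seq_len(k)) {
    idx <- (k - j + 1):(n - j)
    yh <- yh * ay + yl[idx]
    xh <- xh * ax + xl[idx]
  }
  y1 <- yl[(k + 1):n]
  nyh <- ay^k
  nxh <- ax^k
  # joint index over (y_next, y_hist, x_hist)
  j_full <- 1L + y1 + ay * (yh + nyh * xh)
  c_full <- tabulate(j_full, nbins = ay * nyh * nxh)
  j_hx <- 1L + yh + nyh * xh
  c_hx <- tabulate(j_hx, nbins = nyh * nxh)
  j_hy1 <- 1L + y1 + ay * yh
  c_hy1 <- tabulate(j_hy1, nbins = ay * nyh)
  c_h <- tabulate(1L + yh, nbins = nyh)

  nz <- which(c_full > 0)
  if (length(nz) == 0) return(0)
  i0 <- nz - 1L
  y1_i <- i0 %% ay
  rest <- i0 %/% ay
  yh_i <- rest %% nyh
  xh_i <- rest %/% nyh
  num <- c_full[nz] * c_h[1L + yh_i]
  den <- c_hx[1L + yh_i + nyh * xh_i] * c_hy1[1L + y1_i + ay * yh_i]
  te <- sum(c_full[nz] / n_t * log2(num / den))
  max(te, 0)
}

#' Pairwise peak transfer entropy between two neuron sets
#'
#' Computes TE for every ordered (source, target) neuron pair and every
#' history length in `k_range`, and keeps the maximum over `k_range` per
#' pair. Self pairs (same neuron id in both sets) are excluded. States are
#' the 1 s bin counts clipped to binary by default (`count >= 1 -> 1`);
#' `alphabet = "count"` instead clips counts at 3 (4 states).
#'
#' @param source,target binned state matrices (neurons x bins) or
#'   `binned_matrix` objects sharing the bin axis.
#' @param k_range integer history lengths to scan (default 1: a 1 s
#'   history at 1 s bins).
#' @param alphabet "binary" (default) or "count".
#' @param source_ids,target_ids optional neuron ids used to exclude self
#'   pairs (default: row index identity only when the same object is
#'   passed twice).
#' @return data.frame with columns `source`, `target` (row indices),
#'   `peak_te` and one `te_k<k>` column per history length.
#' @export
pairwise_peak_te <- function(source, target, k_range = 1,
                             alphabet = c("binary", "count"),
                             source_ids = NULL, target_ids = NULL) {
  alphabet <- match.arg(alphabet)
  same <- is.null(source_ids) && is.null(target_ids) &&
    identical(source, target)
  sm <- te_states(source, alphabet)
  tm <- te_states(target, alphabet)
  if (ncol(sm) != ncol(tm)) stop("source and target must share the bin axis")
  if (length(k_range) == 0) stop("k_range must be nonempty")
  if (nrow(sm) == 0 || nrow(tm) == 0) stop("empty state matrices")
  if (is.null(source_ids)) source_ids <- if (same) seq_len(nrow(sm)) else
    -seq_len(nrow(sm))
  if (is.null(target_ids)) target_ids <- seq_len(nrow(tm))

  per_k <- list()
  for (k in k_range) {
    if (k == 1 && alphabet == "binary") {
      per_k[[as.character(k)]] <- te_k1_binary_all(sm, tm)
    } else {
      m <- matrix(0, nrow = nrow(sm), ncol = nrow(tm))
      for (i in seq_len(nrow(sm)))
        for (j in seq_len(nrow(tm)))
          m[i, j] <- discrete_te(sm[i, ], tm[j, ], k)
      per_k[[as.character(k)]] <- m
    }
  }
  idx <- expand.grid(source = seq_len(nrow(sm)), target = seq_len(nrow(tm)))
  keep <- source_ids[idx$source] != target_ids[idx$target]
  idx <- idx[keep, , drop = FALSE]
  out <- idx
  for (k in names(per_k))
    out[[paste0("te_k", k)]] <- per_k[[k]][cbind(idx$source, idx$target)]
  out$peak_te <- do.call(pmax, out[paste0("te_k", names(per_k))])
  rownames(out) <- NULL
  out
}

# coerce to a discrete state matrix
te_states <- function(x, alphabet = "binary") {
  if (inherits(x, "binned_matrix")) x <- x$counts
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (alphabet == "binary") (x >= 1) + 0L else pmin(x, 3L)
}

# All-pairs TE for binary states, k = 1, via joint-count matrix products.
# Returns an n_source x n_target matrix. Counts over transitions t -> t+1:
# N(y1, y0, x0) assembled from four cross products; x0 marginals by
# subtraction. Agrees with discrete_te to float precision (tested).
te_k1_binary_all <- function(S, T_) {
  n <- ncol(S)
  S0 <- t(S[, -n, drop = FALSE])            # (n-1) x ns, x_t
  T0 <- T_[, -n, drop = FALSE]              # nt x (n-1), y_t
  T1 <- T_[, -1, drop = FALSE]              # nt x (n-1), y_{t+1}
  n_t <- n - 1
  A11 <- (T1 * T0) %*% S0                   # y1=1,y0=1,x=1  [nt x ns]
  A10 <- (T1 * (1 - T0)) %*% S0             # y1=1,y0=0,x=1
  A01 <- ((1 - T1) * T0) %*% S0             # y1=0,y0=1,x=1
  A00 <- ((1 - T1) * (1 - T0)) %*% S0       # y1=0,y0=0,x=1
  # per-target totals over y-cells (independent of x)
  s11 <- rowSums(T1 * T0)
  s10 <- rowSums(T1 * (1 - T0))
  s01 <- rowSums((1 - T1) * T0)
  s00 <- rowSums((1 - T1) * (1 - T0))
  B11 <- s11 - A11                          # x=0 counts
  B10 <- s10 - A10
  B01 <- s01 - A01
  B00 <- s00 - A00
  # c(y1,y0) per target; c(y0,x) per pair; c(y0) per target
  cy0_1 <- s11 + s01                        # y0=1
  cy0_0 <- s10 + s00
  cx1_y1 <- A11 + A01                       # y0=1, x=1
  cx1_y0 <- A10 + A00
  cx0_y1 <- B11 + B01
  cx0_y0 <- B10 + B00
  term <- function(cnt, c_y0x, c_y1y0, c_y0) {
    out <- cnt * log2((cnt * c_y0) / (c_y0x * c_y1y0))
    out[!is.finite(out) | cnt == 0] <- 0
    out
  }
  te <- term(A11, cx1_y1, s11, cy0_1) + term(A01, cx1_y1, s01, cy0_1) +
    term(A10, cx1_y0, s10, cy0_0) + term(A00, cx1_y0, s00, cy0_0) +
    term(B11, cx0_y1, s11, cy0_1) + term(B01, cx0_y1, s01, cy0_1) +
    term(B10, cx0_y0, s10, cy0_0) + term(B00, cx0_y0, s00, cy0_0)
  te <- te / n_t
  te[te < 0] <- 0
  t(te)   # source x target
}

#' Aggregate pair TEs to a region-level TE
#'
#' Sorts the pair peak TEs in descending order, keeps the upper 50 percent
#' (ceil(n/2), stable sort: value descending, pair order ascending), and
#' averages them.
#'
#' @param pairs data.frame from [pairwise_peak_te()] (needs a `peak_te`
#'   column), or a numeric vector of pair TEs.
#' @return list with `te` (region-level TE in bits), `retained` (the kept
#'   values), `n_pairs`, and `flagged` (TRUE when fewer than 2 pairs were
#'   available and the single value was passed through).
#' @export
region_te <- function(pairs) {
  v <- if (is.data.frame(pairs)) pairs$peak_te else as.numeric(pairs)
  n <- length(v)
  if (n == 0) stop("no pairs")
  if (n < 2)
    return(list(te = v, retained = v, n_pairs = n, flagged = TRUE))
  ord <- order(-v, seq_along(v))
  keep <- ord[seq_len(ceiling(n / 2))]
  retained <- v[keep]
  list(te = mean(retained), retained = retained, n_pairs = n,
       flagged = FALSE)
}

#' Surrogate significance test for a region-level TE
#'
#' Recomputes the full region pipeline (pairwise peak TE, upper-50-percent
#' filter, mean) on surrogate data in which each neuron's time bins are
#' independently permuted (destroying all temporal structure while
#' preserving marginal rates), and reports the plain proportion of
#' surrogates with TE at or above the real value as the p-value. A
#' conservative companion `(count + 1) / (n_surr + 1)` is stored so that a
#' literal p = 0 stays bounded away from zero for downstream use.
#'
#' @param source,target binned state matrices (neurons x bins) or
#'   `binned_matrix` objects.
#' @param n_surr number of surrogate datasets (default 1000).
#' @param k_range,alphabet as in [pairwise_peak_te()].
#' @param surrogate "permute" (full random permutation per neuron,
#'   default) or "rotate" (independent circular shifts).
#' @param seed integer seed.
#' @return list with `p`, `p_conservative`, `te_real`, `te_surr`
#'   (vector of surrogate region TEs), `n_surr`.
#' @export
surrogate_test <- function(source, target, n_surr = 1000, k_range = 1,
                           alphabet = "binary",
                           surrogate = c("permute", "rotate"), seed = 1) {
  surrogate <- match.arg(surrogate)
  if (n_surr < 1) stop("n_surr must be >= 1")
  sm <- te_states(source, alphabet)
  tm <- te_states(target, alphabet)
  same <- identical(sm, tm)
  sids <- seq_len(nrow(sm))
  tids <- if (same) sids else nrow(sm) + seq_len(nrow(tm))
  rte <- function(a, b) region_te(pairwise_peak_te(
    a, b, k_range, alphabet, source_ids = sids, target_ids = tids))$te
  te_real <- rte(sm, tm)
  if (!is.null(seed)) set.seed(seed)
  te_surr <- numeric(n_surr)
  for (s in seq_len(n_surr)) {
    ss <- shuffle_rows(sm, surrogate)
    ts <- if (same) ss else shuffle_rows(tm, surrogate)
    te_surr[s] <- rte(ss, ts)
  }
  cnt <- sum(te_surr >= te_real)
  list(p = cnt / n_surr, p_conservative = (cnt + 1) / (n_surr + 1),
       te_real = te_real, te_surr = te_surr, n_surr = n_surr)
}

shuffle_rows <- function(m, how) {
  n <- ncol(m)
  if (how == "permute") {
    for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(n)]
  } else {
    for (i in seq_len(nrow(m))) {
      k <- sample.int(n, 1)
      m[i, ] <- m[i, ((seq_len(n) + k - 1L) %% n) + 1L]
    }
  }
  m
}

#' Build a directed region-level transfer-entropy network
#'
#' Extracts and concatenates the bins selected by `window_spec` from a 1 s
#' binned matrix, draws `n_draw` neurons with per-region counts
#' proportional to the pool composition (largest-remainder rounding),
#' computes every ordered region-pair TE with surrogate significance, and
#' attaches per-region node importances when provided.
#'
#' @param binned a 1 s `binned_matrix` covering the session.
#' @param timeline a [session_timeline()].
#' @param window_spec one of `"cs"` (all CS bins; restrict with
#'   `cs_type`), `"post_us"` (bins after US offset), `"episode"`
#'   (bins within 2 bins of each behavioral-episode onset bin, i.e. onset
#'   bin +/- 2).
#' @param cs_type CS types included for `"cs"` windows.
#' @param episode_kind episode kinds included for `"episode"` windows.
#' @param n_draw neurons drawn proportionally across regions (all neurons
#'   taken when the pool is smaller). Default 500.
#' @param post_us_bins bins after US offset for `"post_us"`.
#' @param n_surr surrogates per edge.
#' @param alpha significance level for the significant-edge view.
#' @param k_range,alphabet as in [pairwise_peak_te()].
#' @param importance optional `importance_profile` supplying node
#'   attributes.
#' @param seed integer seed (neuron draw + surrogates).
#' @return object of class `te_network`: list with `edges` (data.frame:
#'   source, target, te_bits, p_value, p_conservative, n_pairs,
#'   significant), `nodes` (data.frame: region, n_drawn, importance),
#'   `window_spec`, `alpha`, `n_bins_used`, `seed`.
#' @export
build_te_network <- function(binned, timeline,
                             window_spec = c("cs", "post_us", "episode"),
                             cs_type = c("R", "F"),
                             episode_kind = c("port_visit", "freezing_onset"),
                             n_draw = 500, post_us_bins = 8, n_surr = 1000,
                             alpha = 0.05, k_range = 1, alphabet = "binary",
                             importance = NULL, seed = 1) {
  window_spec <- match.arg(window_spec)
  stopifnot(inherits(binned, "binned_matrix"))
  n_bins <- ncol(binned$counts)
  sel <- switch(window_spec,
    cs = {
      tr <- timeline$cs_trials
      tr <- tr[tr$cs_type %in% cs_type, , drop = FALSE]
      unlist(lapply(seq_len(nrow(tr)), function(i)
        bin_range(tr$onset[i], tr$duration[i], binned$t0, n_bins)))
    },
    post_us = {
      us <- timeline$us_events
      unlist(lapply(seq_len(nrow(us)), function(i)
        bin_range(us$time[i] + 1, post_us_bins, binned$t0, n_bins)))
    },
    episode = {
      ep <- timeline$behavior_episodes
      ep <- ep[ep$kind %in% episode_kind, , drop = FALSE]
      unlist(lapply(ep$onset, function(on) {
        b <- floor(on - binned$t0) + 1L
        (b - 2L):(b + 2L)
      }))
    })
  sel <- sort(unique(sel[sel >= 1 & sel <= n_bins]))
  if (length(sel) == 0) stop("empty window selection for ", window_spec)

  set.seed(seed)
  regions <- unique(binned$neurons$region)
  pool <- table(factor(binned$neurons$region, levels = regions))
  n_take <- min(n_draw, sum(pool))
  alloc <- largest_remainder(as.numeric(pool), n_take)
  drawn <- unlist(lapply(seq_along(regions), function(r) {
    idx <- which(binned$neurons$region == regions[r])
    sort(idx[sample.int(length(idx), alloc[r])])
  }))
  states <- te_states(binned$counts[drawn, sel, drop = FALSE], alphabet)
  reg_of <- binned$neurons$region[drawn]

  pairs_grid <- expand.grid(source = regions, target = regions,
                            stringsAsFactors = FALSE)
  pairs_grid <- pairs_grid[pairs_grid$source != pairs_grid$target, ,
                           drop = FALSE]
  edges <- list()
  for (e in seq_len(nrow(pairs_grid))) {
    ra <- pairs_grid$source[e]; rb <- pairs_grid$target[e]
    si <- which(reg_of == ra); ti <- which(reg_of == rb)
    if (length(si) == 0 || length(ti) == 0) next
    st <- surrogate_test(states[si, , drop = FALSE],
                         states[ti, , drop = FALSE],
                         n_surr = n_surr, k_range = k_range,
                         alphabet = alphabet,
                         seed = derive_seed(seed, e))
    edges[[length(edges) + 1]] <-
      data.frame(source = ra, target = rb, te_bits = st$te_real,
                 p_value = st$p, p_conservative = st$p_conservative,
                 n_pairs = length(si) * length(ti))
  }
  edges <- do.call(rbind, edges)
  edges$significant <- edges$p_value < alpha
  nodes <- data.frame(region = regions,
                      n_drawn = alloc,
                      importance = NA_real_)
  if (!is.null(importance)) {
    m <- match(nodes$region, importance$regions)
    nodes$importance <- importance$region_mean[m]
  }
  structure(list(edges = edges, nodes = nodes, window_spec = window_spec,
                 alpha = alpha, n_bins_used = length(sel), seed = seed),
            class = "te_network")
}

#' @export
print.te_network <- function(x, ...) {
  cat("TE network (", x$window_spec, " windows, ", x$n_bins_used,
      " bins): ", nrow(x$nodes), " regions, ", nrow(x$edges), " edges (",
      sum(x$edges$significant), " significant at alpha = ", x$alpha,
      ")\n", sep = "")
  invisible(x)
}

#' Significant-edge view of a TE network
#'
#' @param net a `te_network`.
#' @return the network with only edges at `p < alpha` retained.
#' @export
significant_edges <- function(net) {
  stopifnot(inherits(net, "te_network"))
  net$edges <- net$edges[net$edges$significant, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}
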