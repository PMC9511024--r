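# FastICA fixed-point iteration (deflation, tanh nonlinearity) on whitened
# data Z (K x n samples, rows orthonormal up to scaling so ZZ'/n = I).
# Returns the K x K unmixing matrix with the best total negentropy proxy over
# restarts. The negentropy proxy per source is (E[logcosh(s)] - gamma)^2 with
# gamma = E[logcosh(g)], g standard normal.
.fastica_deflate <- function(Z, n_restarts = 5L, max_iter = 200L,
                             tol = 1e-6) {
  K <- nrow(Z)
  n <- ncol(Z)
  gamma <- 0.3745672966  # E[log cosh X], X ~ N(0, 1)
  best_W <- NULL
  best_J <- -Inf
  for (r in seq_len(n_restarts)) {
    W <- matrix(0, K, K)
    ok <- TRUE
    for (k in seq_len(K)) {
      w <- stats::rnorm(K)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- drop(crossprod(w, Z))
        g <- tanh(wx)
        w_new <- (Z %*% g) / n - mean(1 - g^2) * w
        if (k > 1L) {
          Wp <- W[, seq_len(k - 1L), drop = FALSE]
          w_new <- w_new - Wp %*% crossprod(Wp, w_new)
        }
        nrm <- sqrt(sum(w_new^2))
        if (nrm < 1e-12) { ok <- FALSE; break }
        w_new <- drop(w_new) / nrm
        conv <- abs(abs(sum(w_new * w)) - 1) < tol
        w <- w_new
        if (conv) break
      }
      if (!ok) break
      W[, k] <- w
    }
    if (!ok) next
    S <- crossprod(W, Z)
    J <- sum((rowMeans(log(cosh(S))) - gamma)^2)
    if (J > best_J) {
      best_J <- J
      best_W <- W
    }
  }
  if (is.null(best_W)) stop("FastICA failed to converge in every restart")
  t(best_W)  # rows unmix: S = best_W' Z
}

#' Group spatial ICA over a cohort of parcel time series
#'
#' Per-subject temporal dimensionality reduction (top
#' `min(subject_reduction, T - 1)` principal components), temporal
#' concatenation across subjects, group-level reduction/whitening to
#' `n_components` spatial dimensions, then FastICA (deflation, tanh, seeded
#' restarts keeping the best negentropy) yielding independent spatial maps.
#' Group time courses are obtained by regressing the concatenated raw data on
#' the maps. Spatial maps are unit-normalized (L2) with the largest-magnitude
#' loading positive, and components are ordered by decreasing explained
#' variance, so the output is deterministic given the seed.
#'
#' @param cohort_ts list of [parcel_ts()] sharing one parcel space.
#' @param n_components number of spatial components (conventionally 20 or 40;
#'   must not exceed the available rank).
#' @param subject_reduction per-subject temporal reduction (default 64;
#'   clamped to T - 1).
#' @param seed integer seed.
#' @param n_restarts FastICA restarts (default 5).
#' @return list of class `ica_decomposition`: `components` (a list of
#'   `network_component`: `spatial_map`, `timecourse`, `matched_name`,
#'   `match_score`), `maps` (components x parcels matrix), `parcel_labels`,
#'   `n_components`.
#' @export
run_group_ica <- function(cohort_ts, n_components, subject_reduction = 64L,
                          seed = 1L, n_restarts = 5L) {
  stopifnot(length(cohort_ts) >= 1L)
  P <- n_parcels(cohort_ts[[1]])
  labels <- cohort_ts[[1]]$parcel_labels
  if (!all(vapply(cohort_ts, n_parcels, integer(1)) == P)) {
    stop("all subjects must share the same parcel count")
  }
  withr::with_seed(seed, {
    reduced <- lapply(cohort_ts, function(ts) {
      X <- ts$data - rowMeans(ts$data)          # P x T, parcel-centered
      k <- min(subject_reduction, ncol(X) - 1L, P)
      sv <- svd(X, nu = k, nv = 0)
      # k x P rows spanning the subject's spatial subspace, PC-weighted
      t(sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = P))
    })
    G <- do.call(rbind, reduced)                # (S*k) x P
    G <- G - rowMeans(G)
    sv <- svd(G, nu = 0, nv = n_components + 1L)
    rank_avail <- sum(sv$d > max(sv$d) * 1e-10)
    if (n_components > rank_avail) {
      stop(sprintf("n_components = %d exceeds available rank %d",
                   n_components, rank_avail))
    }
    Z <- sqrt(P) * t(sv$v[, seq_len(n_components), drop = FALSE])
    # canonicalize the sign of each whitened dimension (largest-magnitude
    # sample positive): the SVD's column signs are arbitrary and otherwise
    # steer FastICA into different basins for reordered-parcel input
    for (k in seq_len(nrow(Z))) {
      if (Z[k, which.max(abs(Z[k, ]))] < 0) Z[k, ] <- -Z[k, ]
    }
    W <- .fastica_deflate(Z, n_restarts = n_restarts)
    S <- W %*% Z                                 # components x parcels
    # unit-norm maps, deterministic sign
    for (k in seq_len(nrow(S))) {
      s <- S[k, ]
      s <- s / sqrt(sum(s^2))
      if (s[which.max(abs(s))] < 0) s <- -s
      S[k, ] <- s
    }
    # group time courses: concatenated raw data regressed on the maps
    Y <- do.call(cbind, lapply(cohort_ts, function(ts) {
      ts$data - rowMeans(ts$data)
    }))                                          # P x T_total
    A <- t(solve(tcrossprod(S), S %*% Y))        # T_total x K
    ord <- order(colSums(A^2), decreasing = TRUE)
    S <- S[ord, , drop = FALSE]
    A <- A[, ord, drop = FALSE]
    comps <- lapply(seq_len(nrow(S)), function(k) {
      structure(list(spatial_map = stats::setNames(S[k, ], labels),
                     timecourse = A[, k],
                     matched_name = NA_character_,
                     match_score = NA_real_),
                class = "network_component")
    })
    structure(list(components = comps, maps = S, parcel_labels = labels,
                   n_components = nrow(S)),
              class = "ica_decomposition")
  })
}

#' @export
print.ica_decomposition <- function(x, ...) {
  matched <- vapply(x$components, function(c) c$matched_name, character(1))
  cat(sprintf("<ica_decomposition> %d components over %d parcels; matched: %s\n",
              x$n_components, length(x$parcel_labels),
              if (all(is.na(matched))) "none yet"
              else paste(stats::na.omit(matched), collapse = ", ")))
  invisible(x)
}

#' Match ICA components to canonical-network templates
#'
#' Greedy assignment by descending absolute spatial correlation: the
#' best-correlated (component, template) pair is matched first, then the
#' next among the remaining, so each template labels at most one component
#' and each component carries at most one label. Components negatively
#' correlated with their template are sign-flipped (map and time course).
#' Pairs below `floor` are never matched; unassigned components stay
#' unmatched. Several components can still map to one network family, as
#' when left and right dorsal-attention activity appears as two separate
#' components matching the hemispheric templates -- both are then used.
#'
#' @param decomposition an `ica_decomposition` (or list of
#'   `network_component`).
#' @param templates parcels x templates numeric matrix with column names, as
#'   from [network_templates()].
#' @param floor minimum absolute spatial correlation for a match
#'   (default 0.3).
#' @return the decomposition with `matched_name` / `match_score` filled in.
#' @export
match_templates <- function(decomposition, templates, floor = 0.3) {
  comps <- if (inherits(decomposition, "ica_decomposition")) {
    decomposition$components
  } else decomposition
  templates <- as.matrix(templates)
  if (is.null(colnames(templates))) stop("templates must have column names")
  if (nrow(templates) != length(comps[[1]]$spatial_map)) {
    stop("template parcel space does not match the components")
  }
  R <- stats::cor(do.call(cbind, lapply(comps, function(c) c$spatial_map)),
                  templates)                      # components x templates
  for (k in seq_along(comps)) {
    comps[[k]]$matched_name <- NA_character_
    comps[[k]]$match_score <- max(abs(R[k, ]))
  }
  absR <- abs(R)
  repeat {
    best <- which.max(absR)
    if (length(best) == 0L || absR[best] < floor) break
    ij <- arrayInd(best, dim(absR))
    k <- ij[1]
    tpl <- ij[2]
    comps[[k]]$matched_name <- colnames(templates)[tpl]
    comps[[k]]$match_score <- absR[best]
    if (R[k, tpl] < 0) {
      comps[[k]]$spatial_map <- -comps[[k]]$spatial_map
      comps[[k]]$timecourse <- -comps[[k]]$timecourse
    }
    absR[k, ] <- -Inf
    absR[, tpl] <- -Inf
  }
  if (inherits(decomposition, "ica_decomposition")) {
    decomposition$components <- comps
    decomposition$maps <- do.call(rbind, lapply(comps, function(c) {
      unname(c$spatial_map)
    }))
    decomposition
  } else {
    comps
  }
}

#' Subject-specific network time courses by backprojection
#'
#' Dual-regression stage 1: the subject's (parcel-centered) data are
#' regressed on the group spatial maps, jointly across components, giving one
#' subject-specific time course per component.
#'
#' @param components an `ica_decomposition`, a list of `network_component`, a
#'   single `network_component`, or a components x parcels map matrix.
#' @param subject_ts a [parcel_ts()] in the same parcel space.
#' @return timepoints x components numeric matrix (column names are matched
#'   network names where available).
#' @export
backproject <- function(components, subject_ts) {
  stopifnot(inherits(subject_ts, "parcel_ts"))
  if (inherits(components, "network_component")) {
    components <- list(components)
  }
  if (inherits(components, "ica_decomposition")) {
    components <- components$components
  }
  if (is.list(components)) {
    maps <- do.call(rbind, lapply(components, function(c) {
      unname(c$spatial_map)
    }))
    nm <- vapply(components, function(c) {
      if (is.na(c$matched_name)) "" else c$matched_name
    }, character(1))
  } else {
    maps <- as.matrix(components)
    nm <- rownames(maps)
  }
  if (ncol(maps) != n_parcels(subject_ts)) {
    stop("component parcel space does not match the subject data")
  }
  qrm <- qr(t(maps))
  if (qrm$rank < nrow(maps)) {
    stop("spatial maps are rank-deficient: backprojection is not identified")
  }
  Y <- subject_ts$data - rowMeans(subject_ts$data)
  tc <- t(solve(tcrossprod(maps), maps %*% Y))   # T x K
  colnames(tc) <- nm
  tc
}

#' BOLD signal variability of a network time course
#'
#' The sample standard deviation (divisor n - 1) of the time course; a
#' constant course has variability 0.
#'
#' @param timecourse numeric vector, length >= 2.
#' @return non-negative scalar.
#' @export
bold_variability <- function(timecourse) {
  if (length(timecourse) < 2L) stop("time course must have length >= 2")
  stats::sd(timecourse)
}

#' Per-subject network variability table
#'
#' Backprojects the template-matched components onto every subject and
#' records the standard deviation of each subject-specific network time
#' course.
#'
#' @param decomposition a template-matched `ica_decomposition`.
#' @param cohort_ts named list of [parcel_ts()] (names = subject ids).
#' @return tibble with `subject_id`, `network`, `component`, `variability`.
#' @export
variability_table <- function(decomposition, cohort_ts) {
  matched <- which(!vapply(decomposition$components,
                           function(c) is.na(c$matched_name), logical(1)))
  if (length(matched) == 0L) {
    return(tibble::tibble(subject_id = character(), network = character(),
                          component = integer(), variability = numeric()))
  }
  comps <- decomposition$components[matched]
  rows <- lapply(names(cohort_ts), function(sid) {
    tc <- backproject(comps, cohort_ts[[sid]])
    tibble::tibble(
      subject_id = sid,
      network = vapply(comps, function(c) c$matched_name, character(1)),
      component = matched,
      variability = apply(tc, 2, bold_variability)
    )
  })
  dplyr::bind_rows(rows)
}
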