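#' Segmentation parameters
#'
#' Controls the bright-field cell detector: mean filter -> gradient
#' magnitude -> convolution with an annular ("ring") kernel matched to
#' the expected cell radius -> robust threshold -> local maxima as cell
#' centre candidates -> circular seed -> greedy active-contour
#' refinement. Ring radii default to `(0.7, 1.3)` times the mean cell
#' radius. The detection threshold is `detection_threshold_k` robust SDs
#' (1.4826 MAD) above the median matched-filter response.
#'
#' @param cell_radius_mean_px expected cell radius (matched-filter
#'   scale), pixels.
#' @param mean_filter_radius_px box mean-filter radius.
#' @param ring_kernel_inner_radius_px,ring_kernel_outer_radius_px
#'   annulus radii of the ring kernel.
#' @param detection_threshold_k candidate threshold in robust SDs of
#'   the matched-filter response; kept loose (candidates are cheap, the
#'   contour validation is the real gate).
#' @param max_candidates cap on centre candidates per frame (strongest
#'   responses first).
#' @param snake_nodes number of contour nodes.
#' @param snake_alpha,snake_beta,snake_gamma continuity, curvature and
#'   image-energy weights.
#' @param snake_pressure contraction pressure (energy per enclosed
#'   pixel of area): drives the contour inward on featureless regions,
#'   while the image term holds it at a rim.
#' @param max_iterations,convergence_eps_px snake stopping rule.
#' @param search_step_px half-pixel node search step.
#' @param seed_radius_factor circular seeds start at this multiple of
#'   the mean radius; > 1 so the snake approaches every rim from
#'   outside (snakes contract, they do not expand).
#' @param contour_gradient_ratio a refined contour is accepted only if
#'   its mean raw gradient magnitude exceeds this multiple of the
#'   frame's median gradient (the noise floor); rejects matched-filter
#'   sidelobes and noise contours on any frame size or cell density.
#' @param es_polish logical; apply an optional (1+1)-evolution-strategy
#'   polish of the node positions after the greedy snake.
#' @param es_iterations iterations of the ES polish.
#' @return object of class `rhd_seg_params`.
#' @export
segmentation_params <- function(cell_radius_mean_px = 22,
                                mean_filter_radius_px = 2,
                                ring_kernel_inner_radius_px = 0.7 * cell_radius_mean_px,
                                ring_kernel_outer_radius_px = 1.3 * cell_radius_mean_px,
                                detection_threshold_k = 2,
                                max_candidates = 40,
                                snake_nodes = 40,
                                snake_alpha = 0.2, snake_beta = 0.3,
                                snake_gamma = 3, snake_pressure = 0.2,
                                max_iterations = 60,
                                convergence_eps_px = 0.25,
                                search_step_px = 0.5,
                                seed_radius_factor = 1.3,
                                contour_gradient_ratio = 12,
                                es_polish = FALSE, es_iterations = 60) {
  stopifnot(ring_kernel_outer_radius_px > ring_kernel_inner_radius_px,
            ring_kernel_inner_radius_px > 0,
            snake_alpha >= 0, snake_beta >= 0, snake_gamma >= 0,
            max_iterations >= 1, snake_nodes >= 4)
  structure(as.list(environment()), class = "rhd_seg_params")
}

# gradient magnitude of the mean-filtered frame; normalised to [0, 1]
# for the snake, with the raw field and its median (noise floor) kept
# as attributes for contour validation
gradient_field <- function(frame, params) {
  sm <- box_mean_filter_cpp(frame, as.integer(params$mean_filter_radius_px))
  H <- nrow(sm); W <- ncol(sm)
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
  g_raw <- sqrt(gr^2 + gc^2)
  top <- quantile(g_raw, 0.999)
  g <- if (top > 0) pmin(g_raw / top, 1) else g_raw
  attr(g, "scale") <- top
  attr(g, "noise_floor") <- median(g_raw)
  g
}

ring_kernel <- function(inner, outer) {
  r <- ceiling(outer)
  d <- sqrt(outer((-r:r)^2, (-r:r)^2, "+"))
  k <- (d >= inner & d <= outer) * 1
  k / sum(k)
}

# 2-D circular convolution via FFT, kernel centred at its middle pixel
convolve2d_fft <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  kf <- matrix(0, H, W)
  kh <- nrow(kern); kw <- ncol(kern)
  ci <- (kh + 1) %/% 2; cj <- (kw + 1) %/% 2
  for (i in seq_len(kh)) {
    ii <- ((i - ci) %% H) + 1
    jj <- ((seq_len(kw) - cj) %% W) + 1
    kf[ii, jj] <- kf[ii, jj] + kern[i, ]
  }
  Re(fft(fft(img) * fft(kf), inverse = TRUE)) / (H * W)
}

circle_nodes <- function(center, radius, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
}

contour_from_nodes <- function(nodes, cell_id, H, W, image_energy = NA_real_,
                               energy_trace = NULL) {
  mask <- fill_polygon_cpp(nodes[, 1] - 1, nodes[, 2] - 1, H, W)
  area <- sum(mask)
  centroid <- if (area > 0) {
    idx <- which(mask, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  } else c(NA_real_, NA_real_)
  structure(list(cell_id = cell_id, nodes = nodes, mask = mask,
                 area_px = area, centroid = centroid, touches_edge = FALSE,
                 image_energy = image_energy, energy_trace = energy_trace),
            class = "rhd_contour")
}

# total snake energy, R implementation (kept as an independent check of
# the C++ energy used inside the refinement loop)
snake_energy <- function(nodes, G, alpha, beta, gamma, kappa = 0,
                         dbar = NULL) {
  n <- nrow(nodes)
  prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n)[-1], 1)
  d <- sqrt(rowSums((nodes - nodes[prv, , drop = FALSE])^2))
  if (is.null(dbar)) dbar <- mean(d)
  sec <- nodes[prv, , drop = FALSE] + nodes[nxt, , drop = FALSE] - 2 * nodes
  gi <- apply(nodes, 1, function(p) bilin_r(G, p[1], p[2]))
  A <- 0.5 * sum(nodes[, 2] * nodes[nxt, 1] - nodes[nxt, 2] * nodes[, 1])
  sum(alpha * (d - dbar)^2 + beta * rowSums(sec^2) - gamma * gi) +
    kappa * abs(A)
}

bilin_r <- function(G, r, c) {
  H <- nrow(G); W <- ncol(G)
  r <- min(max(r, 1), H); c <- min(max(c, 1), W)
  i <- min(floor(r), H - 1); j <- min(floor(c), W - 1)
  fr <- r - i; fc <- c - j
  G[i, j] * (1 - fr) * (1 - fc) + G[i + 1, j] * fr * (1 - fc) +
    G[i, j + 1] * (1 - fr) * fc + G[i + 1, j + 1] * fr * fc
}

#' Refine a cell contour with a greedy active contour
#'
#' Nodes move on a half-pixel grid, each move minimising the sum of every
#' energy term the node participates in (continuity, curvature, negative
#' normalised gradient magnitude, and a contraction pressure on the
#' enclosed area), so total energy is non-increasing within each
#' iteration by construction. The pressure contracts the contour over
#' featureless regions; the image term holds it at intensity rims.
#' Refinement stops after `max_iterations` or when
#' the largest node displacement drops below `convergence_eps_px`. If the
#' refined contour ends with a worse image energy (negative gradient
#' magnitude along the nodes) than the seed, the seed is returned.
#'
#' @param seed_contour an `rhd_contour` (see [detect_cells()]).
#' @param bf_frame bright-field frame (numeric matrix).
#' @param params [segmentation_params()].
#' @param gradient optional precomputed normalised gradient field of `bf_frame`.
#' @return refined `rhd_contour` with an `energy_trace` attribute
#'   (per-iteration start/end total energies).
#' @export
refine_contour <- function(seed_contour, bf_frame, params = segmentation_params(),
                           gradient = NULL) {
  stopifnot(inherits(seed_contour, "rhd_contour"), is.matrix(bf_frame))
  H <- nrow(bf_frame); W <- ncol(bf_frame)
  if (seed_contour$area_px < 3) {
    warning("degenerate seed contour (area < 3 px); returned unchanged")
    return(seed_contour)
  }
  if (is.null(gradient)) gradient <- gradient_field(bf_frame, params)
  nodes0 <- seed_contour$nodes
  seed_img_e <- -mean(apply(nodes0, 1, function(p) bilin_r(gradient, p[1], p[2])))
  res <- snake_refine_cpp(gradient, cbind(nodes0[, 1] - 1, nodes0[, 2] - 1),
                          params$snake_alpha, params$snake_beta,
                          params$snake_gamma, params$max_iterations,
                          params$convergence_eps_px, params$search_step_px,
                          params$snake_pressure)
  nodes <- cbind(res$nodes[, 1] + 1, res$nodes[, 2] + 1)
  if (isTRUE(params$es_polish))
    nodes <- es_polish_nodes(nodes, gradient, params)
  img_e <- -mean(apply(nodes, 1, function(p) bilin_r(gradient, p[1], p[2])))
  if (img_e > seed_img_e + 1e-12) {
    out <- seed_contour
    out$image_energy <- seed_img_e
    return(out)
  }
  trace <- cbind(start = res$energy_start, end = res$energy_end)
  contour_from_nodes(nodes, seed_contour$cell_id, H, W,
                     image_energy = img_e, energy_trace = trace)
}

# optional (1+1)-ES polish: isotropic Gaussian jitter on all nodes,
# 1/5-rule step adaptation, accepting only energy improvements
es_polish_nodes <- function(nodes, G, params) {
  sigma <- params$search_step_px
  e <- snake_energy(nodes, G, params$snake_alpha, params$snake_beta,
                    params$snake_gamma, params$snake_pressure)
  for (i in seq_len(params$es_iterations)) {
    cand <- nodes + matrix(rnorm(length(nodes), 0, sigma), nrow(nodes))
    ec <- snake_energy(cand, G, params$snake_alpha, params$snake_beta,
                       params$snake_gamma, params$snake_pressure)
    if (ec < e) {
      nodes <- cand; e <- ec; sigma <- sigma * 1.5
    } else sigma <- sigma * 0.85
  }
  nodes
}

#' Detect erythrocyte contours in a bright-field frame
#'
#' @param bf_frame numeric matrix (bright-field modality).
#' @param params [segmentation_params()].
#' @return list of `rhd_contour` objects with consecutive `cell_id`
#'   starting at 0 and `touches_edge` flags set. Pairwise mask overlap of
#'   returned contours is at most 10% of the smaller area (the worse
#'   contour by image energy is dropped otherwise).
#' @export
detect_cells <- function(bf_frame, params = segmentation_params()) {
  if (!is.matrix(bf_frame)) stop("bf_frame must be a 2-D matrix")
  H <- nrow(bf_frame); W <- ncol(bf_frame)
  G <- gradient_field(bf_frame, params)
  kern <- ring_kernel(params$ring_kernel_inner_radius_px,
                      params$ring_kernel_outer_radius_px)
  resp <- convolve2d_fft(G, kern)
  thr <- median(resp) + params$detection_threshold_k * mad(resp)
  rbar <- params$cell_radius_mean_px
  mx <- local_maxima_cpp(resp, thr, 2 * rbar)
  if (nrow(mx) > params$max_candidates)
    mx <- mx[seq_len(params$max_candidates), , drop = FALSE]
  # contour acceptance: mean raw gradient along the nodes must clear the
  # frame's gradient noise floor by the configured ratio
  grad_floor <- params$contour_gradient_ratio * attr(G, "noise_floor") /
    max(attr(G, "scale"), .Machine$double.eps)
  contours <- list()
  for (k in seq_len(nrow(mx))) {
    center <- c(mx[k, 1] + 1, mx[k, 2] + 1)
    nodes <- circle_nodes(center, params$seed_radius_factor * rbar,
                          params$snake_nodes)
    nodes[, 1] <- pmin(pmax(nodes[, 1], 1), H)
    nodes[, 2] <- pmin(pmax(nodes[, 2], 1), W)
    seed <- contour_from_nodes(nodes, length(contours), H, W)
    if (seed$area_px < 3) next
    ct <- refine_contour(seed, bf_frame, params, gradient = G)
    if (ct$area_px < 0.2 * pi * rbar^2 || ct$area_px > 3 * pi * rbar^2) next
    if (-ct$image_energy < grad_floor) next
    contours[[length(contours) + 1]] <- ct
  }
  # resolve overlaps: keep the contour with the better (lower) image energy
  keep <- rep(TRUE, length(contours))
  if (length(contours) >= 2) {
    for (a in seq_along(contours)) {
      if (!keep[a]) next
      for (b in seq_along(contours)) {
        if (b <= a || !keep[b]) next
        ov <- sum(contours[[a]]$mask & contours[[b]]$mask)
        if (ov > 0.1 * min(contours[[a]]$area_px, contours[[b]]$area_px)) {
          ea <- contours[[a]]$image_energy; eb <- contours[[b]]$image_energy
          if (is.na(ea)) ea <- Inf
          if (is.na(eb)) eb <- Inf
          if (ea <= eb) keep[b] <- FALSE else keep[a] <- FALSE
        }
      }
    }
  }
  contours <- contours[keep]
  for (k in seq_along(contours)) contours[[k]]$cell_id <- k - 1L
  flag_edge_cells(contours, c(H, W))
}

#' Flag contours whose mask touches the frame border
#'
#' Pure function of `mask` and the border; idempotent; all other fields
#' are left unchanged.
#'
#' @param contours list of `rhd_contour`.
#' @param frame_shape integer `c(H, W)`.
#' @return the contours with `touches_edge` set.
#' @export
flag_edge_cells <- function(contours, frame_shape) {
  H <- frame_shape[1]; W <- frame_shape[2]
  lapply(contours, function(ct) {
    m <- ct$mask
    stopifnot(nrow(m) == H, ncol(m) == W)
    ct$touches_edge <- any(m[1, ]) || any(m[H, ]) || any(m[, 1]) || any(m[, W])
    ct
  })
}

#' Serialise contours to CSV (nodes and per-cell summary)
#'
#' Coordinates are written 0-based to match the other exported formats.
#'
#' @param contours list of `rhd_contour`.
#' @param nodes_path,summary_path output CSV paths.
#' @return invisibly, the summary data.frame.
#' @export
write_contours <- function(contours, nodes_path, summary_path) {
  nd <- do.call(rbind, lapply(contours, function(ct)
    data.frame(cell_id = ct$cell_id,
               node_index = seq_len(nrow(ct$nodes)) - 1L,
               row = ct$nodes[, 1] - 1, col = ct$nodes[, 2] - 1)))
  sm <- do.call(rbind, lapply(contours, function(ct)
    data.frame(cell_id = ct$cell_id, area_px = ct$area_px,
               centroid_row = ct$centroid[1] - 1,
               centroid_col = ct$centroid[2] - 1,
               touches_edge = ct$touches_edge)))
  write.csv(nd, nodes_path, row.names = FALSE)
  write.csv(sm, summary_path, row.names = FALSE)
  invisible(sm)
}
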