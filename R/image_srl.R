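# Image-based longest-root-length measurement.
#
# Images are plain R objects: a grayscale image is a numeric matrix in
# [0, 1] (rows = y, columns = x), an RGB image an array of dim (h, w, 3).
# The pipeline is the classic binarize-and-measure protocol: global
# thresholding of the grayscale image, morphological thinning of the root
# silhouette to a one-pixel skeleton, and the longest geodesic path across
# the skeleton's pixel-adjacency graph as the seminal root length.

as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L)
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  stop("image must be a numeric matrix or an (h, w, 3) array",
       call. = FALSE)
}

#' Otsu's global threshold
#'
#' Maximum between-class-variance threshold on a 256-bin histogram of a
#' grayscale image with intensities in `[0, 1]`.
#'
#' @param gray numeric matrix of intensities in `[0, 1]`.
#' @return Threshold value in `(0, 1)`.
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(gray)
  counts <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  (which.max(sigma_b) - 0.5) / 256
}

#' Binarize a root photograph
#'
#' Separates dark root pixels from the light background by a global
#' automatic (Otsu) threshold on the grayscale image. Deterministic for a
#' fixed image.
#'
#' @param image grayscale matrix or RGB array with intensities in
#'   `[0, 1]`.
#' @param mm_per_pixel physical scale of the image, mm per pixel, > 0.
#' @param invert set `TRUE` for light roots on a dark background.
#' @param threshold optional manual threshold overriding Otsu's choice.
#' @return A `root_mask`: logical matrix (TRUE = root) with the scale
#'   attached.
#' @export
binarize <- function(image, mm_per_pixel = 1, invert = FALSE,
                     threshold = NULL) {
  gray <- as_gray(image)
  if (length(gray) == 0L) stop("empty image", call. = FALSE)
  if (diff(range(gray)) == 0)
    stop("constant-intensity image cannot be thresholded", call. = FALSE)
  thr <- if (is.null(threshold)) otsu_threshold(gray) else threshold
  fg <- if (invert) gray > thr else gray < thr
  root_mask(fg, mm_per_pixel)
}

#' Construct a binary root mask
#'
#' @param grid logical matrix, TRUE where root.
#' @param mm_per_pixel physical scale, mm per pixel, finite and > 0.
#' @return An object of class `root_mask`.
#' @export
root_mask <- function(grid, mm_per_pixel) {
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  grid <- grid & !is.na(grid)
  if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be finite and > 0", call. = FALSE)
  structure(list(grid = grid, mm_per_pixel = as.numeric(mm_per_pixel)),
            class = "root_mask")
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Zhang-Suen iterative thinning; the result is an 8-connected,
#' approximately medial, one-pixel-wide skeleton of the foreground.
#'
#' @param grid logical matrix (TRUE = foreground).
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(grid) {
  m <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, -1,  0); p3 <- shift_mat(m, -1,  1)
      p4 <- shift_mat(m,  0,  1); p5 <- shift_mat(m,  1,  1)
      p6 <- shift_mat(m,  1,  0); p7 <- shift_mat(m,  1, -1)
      p8 <- shift_mat(m,  0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Build the weighted pixel-adjacency graph of a skeleton: vertices are
# foreground pixels, edges join 8-neighbours with weight 1 (axial) or
# sqrt(2) (diagonal).
skeleton_graph <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0L) stop("empty skeleton", call. = FALSE)
  h <- nrow(skel)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  id <- integer(length(skel)); id[idx] <- seq_along(idx)
  offs <- list(c(-1L, 0L, 1), c(1L, 0L, 1), c(0L, -1L, 1), c(0L, 1L, 1),
               c(-1L, -1L, sqrt(2)), c(-1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)), c(1L, 1L, sqrt(2)))
  ed <- lapply(offs, function(o) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= ncol(skel)
    ok[ok] <- skel[cbind(r2[ok], c2[ok])]
    if (!any(ok)) return(NULL)
    j <- id[(c2[ok] - 1L) * h + r2[ok]]
    i <- id[idx[ok]]
    keep <- i < j  # undirected, each edge once
    if (!any(keep)) return(NULL)
    cbind(i[keep], j[keep], o[3])
  })
  ed <- do.call(rbind, ed)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(ed) && nrow(ed) > 0)
    g <- igraph::add_edges(g, t(ed[, 1:2, drop = FALSE]),
                           weight = ed[, 3])
  list(graph = g, rows = rows, cols = cols)
}

# Length of a pixel path by chord resampling: Euclidean chords between
# points `stride` pixels apart along the path, which corrects the up-to-8%
# overestimate of the raw 1/sqrt(2) chamfer metric on oblique segments.
chord_length <- function(rows, cols, stride = 8L) {
  n <- length(rows)
  if (n < 2L) return(0)
  ii <- unique(c(seq(1L, n, by = max(1L, stride)), n))
  sum(sqrt(diff(rows[ii])^2 + diff(cols[ii])^2))
}

# Distance from a pixel to the nearest background pixel, searched in a
# local window (strokes are a few pixels wide; cap at `rmax`).
local_halfwidth <- function(grid, r, c, rmax = 8L) {
  h <- nrow(grid); w <- ncol(grid)
  rs <- max(1L, r - rmax):min(h, r + rmax)
  cs <- max(1L, c - rmax):min(w, c + rmax)
  sub <- grid[rs, cs, drop = FALSE]
  bg <- which(!sub, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(rmax)
  min(sqrt((bg[, 1] + rs[1] - 1 - r)^2 + (bg[, 2] + cs[1] - 1 - c)^2))
}

# Thinning erodes skeleton terminals into the stroke tip by up to the
# stroke half-width. Recover the lost length at one path end: walk from
# the terminal along the local tangent while still in foreground, and
# count whatever exceeds the stroke's typical half-width.
tip_extension <- function(grid, pr, pc, halfwidth) {
  n <- length(pr)
  k <- min(n, 7L)
  tangent <- c(pr[1] - pr[k], pc[1] - pc[k])
  nrm <- sqrt(sum(tangent^2))
  if (nrm == 0) return(0)
  tangent <- tangent / nrm
  e <- 0
  for (t in seq(0.5, 15, by = 0.5)) {
    rr <- round(pr[1] + tangent[1] * t)
    cc <- round(pc[1] + tangent[2] * t)
    if (rr < 1 || rr > nrow(grid) || cc < 1 || cc > ncol(grid)) break
    if (!grid[rr, cc]) break
    e <- t
  }
  max(0, e - halfwidth)
}

#' Longest root length from a binary mask
#'
#' Implements the longest-root measure: the mask is thinned to a skeleton,
#' the skeleton's pixel-adjacency graph is built (8-connectivity, step
#' weight 1 axial, sqrt(2) diagonal) and the maximum geodesic path --- the
#' graph diameter, taken over all connected components --- is located. For
#' a tree-shaped skeleton this spans the two farthest root tips.
#'
#' The reported physical length is the chord-resampled length of the
#' diameter path (Euclidean chords every few pixels) times `mm_per_pixel`;
#' the raw chamfer-weighted graph length systematically overestimates
#' oblique segments by up to 8% and is returned alongside as
#' `length_chamfer_mm` (see the methods vignette).
#'
#' @param mask a [root_mask()] with at least one foreground pixel.
#' @return An object of class `srl_measurement`: list with `length_mm`,
#'   `length_chamfer_mm`, `path_pixels` (pixel count of the diameter
#'   path), and `endpoints` (2 x 2 matrix of (row, col) coordinates).
#' @export
longest_root_length <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  if (!any(mask$grid)) stop("mask has no foreground pixels", call. = FALSE)
  skel <- skeletonize(mask$grid)
  if (!any(skel)) skel <- mask$grid  # degenerate: single dots survive
  sg <- skeleton_graph(skel)
  g <- sg$graph
  n <- igraph::vcount(g)
  if (n == 1L || igraph::ecount(g) == 0L) {
    return(structure(list(length_mm = 0, length_chamfer_mm = 0,
                          path_pixels = 1L,
                          endpoints = rbind(c(sg$rows[1], sg$cols[1]),
                                            c(sg$rows[1], sg$cols[1]))),
                     class = "srl_measurement"))
  }
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  D[!is.finite(D)] <- -Inf
  at <- arrayInd(which.max(D), dim(D))
  from <- at[1]; to <- at[2]
  sp <- igraph::shortest_paths(g, from = from, to = to,
                               weights = igraph::E(g)$weight)$vpath[[1]]
  vp <- as.integer(sp)
  pr <- sg$rows[vp]; pc <- sg$cols[vp]
  len_px <- chord_length(pr, pc)
  # tip recovery: median stroke half-width from sampled path pixels,
  # then extend both ends through the foreground they were eroded from
  samp <- unique(round(seq(1, length(vp), length.out = min(40, length(vp)))))
  hw <- stats::median(vapply(samp, function(i)
    local_halfwidth(mask$grid, pr[i], pc[i]), numeric(1)))
  len_px <- len_px +
    tip_extension(mask$grid, pr, pc, hw) +
    tip_extension(mask$grid, rev(pr), rev(pc), hw)
  structure(list(length_mm = len_px * mask$mm_per_pixel,
                 length_chamfer_mm = D[from, to] * mask$mm_per_pixel,
                 path_pixels = length(vp),
                 endpoints = rbind(c(sg$rows[from], sg$cols[from]),
                                   c(sg$rows[to], sg$cols[to]))),
            class = "srl_measurement")
}

#' @export
print.srl_measurement <- function(x, ...) {
  cat(sprintf("Longest root: %.2f mm (%d skeleton pixels; chamfer %.2f mm)\n",
              x$length_mm, x$path_pixels, x$length_chamfer_mm))
  invisible(x)
}

# Trace a smooth stroke centreline of exact arc length (pixels), seeded.
# Returns a matrix of (y, x) sample points relative to the start.
trace_path <- function(length_px, curvature, angle_deg, step = 0.25) {
  n <- max(2L, ceiling(length_px / step))
  step <- length_px / n  # exact arc length by construction
  theta0 <- angle_deg * pi / 180
  # smooth heading wander: integrated angular noise, deviation clamped so
  # the curve keeps advancing (arc length is unaffected by the clamp)
  dtheta <- stats::rnorm(n, 0, curvature * step * 0.05)
  dev <- pmin(pmax(cumsum(dtheta), -pi / 3), pi / 3)
  theta <- theta0 + dev
  y <- c(0, cumsum(sin(theta) * step))
  x <- c(0, cumsum(cos(theta) * step))
  cbind(y = y, x = x)
}

stamp_disk <- function(canvas, ys, xs, radius, value) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  py <- rep(round(ys), each = nrow(off)) + off$dy
  px <- rep(round(xs), each = nrow(off)) + off$dx
  ok <- py >= 1 & py <= nrow(canvas) & px >= 1 & px <= ncol(canvas)
  canvas[cbind(py[ok], px[ok])] <- value
  canvas
}

#' Render a synthetic root image of known arc length
#'
#' Draws a connected dark curve of exactly known centreline arc length on
#' a light background, for testing the measurement pipeline end to end.
#' The curve is a seeded smooth random walk of the heading angle; optional
#' short side branches (25% of the main axis) emulate lateral roots. The
#' stroke is about 3 px wide with a half-tone rim emulating anti-aliased
#' edges, and mild background noise.
#'
#' @param length_mm centreline arc length of the main axis, mm, > 0.
#' @param curvature nonnegative wiggliness factor; 0 draws a straight
#'   segment.
#' @param branches number of short side branches (>= 0).
#' @param mm_per_pixel physical scale of the rendering, mm per pixel.
#' @param seed integer seed; identical seeds give identical rasters.
#' @param angle_deg initial heading in degrees (90 = straight down).
#' @param canvas_px optional `c(h, w)`; when given and the curve does not
#'   fit, an error is raised. By default the canvas is sized to fit.
#' @return List with `image` (an (h, w, 3) RGB array), `true_length_mm`
#'   (the exact main-axis arc length), and `stroke_mask` (logical matrix
#'   of the drawn stroke, for mask-accuracy tests).
#' @export
render_root <- function(length_mm, curvature = 0, branches = 0,
                        mm_per_pixel = 0.2, seed = 1L, angle_deg = 90,
                        canvas_px = NULL) {
  if (length_mm <= 0) stop("length_mm must be > 0", call. = FALSE)
  length_px <- length_mm / mm_per_pixel
  with_seed(seed, {
    main <- trace_path(length_px, curvature, angle_deg)
    paths <- list(main)
    if (branches > 0) {
      anchors <- round(seq(0.35, 0.75, length.out = branches) * nrow(main))
      for (i in seq_len(branches)) {
        side <- if (i %% 2 == 0) -40 else 40
        br <- trace_path(0.25 * length_px, curvature,
                         angle_deg + side)
        br[, 1] <- br[, 1] + main[anchors[i], 1]
        br[, 2] <- br[, 2] + main[anchors[i], 2]
        paths <- c(paths, list(br))
      }
    }
    all_pts <- do.call(rbind, paths)
    margin <- 12
    if (is.null(canvas_px)) {
      h <- ceiling(diff(range(all_pts[, 1]))) + 2 * margin
      w <- ceiling(diff(range(all_pts[, 2]))) + 2 * margin
      oy <- margin - floor(min(all_pts[, 1]))
      ox <- margin - floor(min(all_pts[, 2]))
    } else {
      h <- canvas_px[1]; w <- canvas_px[2]
      oy <- margin; ox <- floor(w / 2)
      if (diff(range(all_pts[, 1])) + 2 * margin > h ||
          max(all_pts[, 2]) + ox > w - 2 || min(all_pts[, 2]) + ox < 2)
        stop("curve exits the canvas", call. = FALSE)
    }
    gray <- matrix(0.9, h, w) +
      matrix(stats::rnorm(h * w, 0, 0.015), h, w)
    for (p in paths)  # half-tone rims first so they never cut a core
      gray <- stamp_disk(gray, p[, 1] + oy, p[, 2] + ox, 2.4, 0.55)
    for (p in paths)
      gray <- stamp_disk(gray, p[, 1] + oy, p[, 2] + ox, 1.5, 0.08)
    gray <- pmin(pmax(gray, 0), 1)
    stroke <- matrix(FALSE, h, w)
    for (p in paths)
      stroke <- stamp_disk(stroke, p[, 1] + oy, p[, 2] + ox, 1.5, TRUE)
    list(image = array(rep(gray, 3), dim = c(h, w, 3)),
         true_length_mm = length_mm,
         stroke_mask = stroke)
  })
}

#' Read and write portable anymap (PNM) images
#'
#' Minimal plain-text PNM support for exchanging images with the
#' command-line pipeline: `P2` (ASCII grayscale) and `P3` (ASCII RGB).
#' Intensities are scaled to `[0, 1]` on read and to the stated maxval on
#' write.
#'
#' @param path file path (conventionally `.pgm` for P2, `.ppm` for P3).
#' @param image grayscale matrix or (h, w, 3) RGB array in `[0, 1]`.
#' @param maxval integer maximum sample value written (default 255).
#' @return `read_pnm` returns a matrix (P2) or array (P3); `write_pnm`
#'   returns `path` invisibly.
#' @export
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3"))
    stop("unsupported PNM type: ", magic, " (only plain P2/P3)",
         call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) / maxval
  if (magic == "P2") {
    if (length(vals) != w * h) stop("corrupt PGM payload", call. = FALSE)
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(vals) != 3 * w * h) stop("corrupt PPM payload", call. = FALSE)
    px <- matrix(vals, ncol = 3, byrow = TRUE)
    array(c(matrix(px[, 1], h, w, byrow = TRUE),
            matrix(px[, 2], h, w, byrow = TRUE),
            matrix(px[, 3], h, w, byrow = TRUE)), dim = c(h, w, 3))
  }
}

#' @rdname read_pnm
#' @export
write_pnm <- function(image, path, maxval = 255L) {
  if (is.matrix(image)) {
    v <- round(t(image) * maxval)  # w x h; column i is image row i
    header <- c("P2", paste(ncol(image), nrow(image)), as.character(maxval))
    body <- apply(v, 2, paste, collapse = " ")
  } else {
    stopifnot(length(dim(image)) == 3L)
    h <- dim(image)[1]; w <- dim(image)[2]
    px <- round(cbind(as.vector(t(image[, , 1])),
                      as.vector(t(image[, , 2])),
                      as.vector(t(image[, , 3]))) * maxval)
    header <- c("P3", paste(w, h), as.character(maxval))
    flat <- as.vector(t(px))
    body <- vapply(seq_len(h), function(i) {
      paste(flat[((i - 1) * 3 * w + 1):(i * 3 * w)], collapse = " ")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
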