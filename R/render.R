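# Deterministic software rasterizer for ball-and-stick molecular snapshots.
# Orthographic camera, fixed directional light, Lambert shading, z-buffer.
# No system graphics stack is involved, so identical inputs give bitwise
# identical rasters on any platform.

# CPK element colors (0-255 RGB), Jmol-style.
.cpk_colors <- list(
  H = c(255, 255, 255), C = c(144, 144, 144), N = c(48, 80, 248),
  O = c(255, 13, 13), F = c(144, 224, 80), Cl = c(31, 240, 31),
  Br = c(166, 41, 41), I = c(148, 0, 148), S = c(255, 255, 48),
  P = c(255, 128, 0), B = c(255, 181, 181), Si = c(240, 200, 160),
  Na = c(171, 92, 242), K = c(143, 64, 212), Ca = c(61, 255, 0),
  Mg = c(138, 255, 0), Fe = c(224, 102, 51), Zn = c(125, 128, 176))
.cpk_default_color <- c(255, 20, 147)

# Van der Waals radii in Angstrom (Bondi-style).
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
                Br = 1.85, I = 1.98, S = 1.80, P = 1.80, B = 1.92, Si = 2.10,
                Na = 2.27, K = 2.75, Ca = 2.31, Mg = 1.73, Fe = 2.00,
                Zn = 1.39)
.vdw_default <- 1.75

#' Rendering style for molecular snapshots
#'
#' @param atom_colors Named list mapping element symbol to an RGB triple in
#'   0-255. Defaults to CPK colors; unlisted elements render in pink.
#' @param atom_radius_scale Displayed atom radius as a fraction of the van der
#'   Waals radius (ball-and-stick convention). Must be positive.
#' @param bond_radius Bond cylinder radius in Angstrom. Must be positive.
#' @param background RGB triple in 0-255.
#' @param image_size Image side length in pixels (square raster), at least 32.
#' @return A list of class `render_style`.
#' @export
render_style <- function(atom_colors = .cpk_colors, atom_radius_scale = 0.30,
                         bond_radius = 0.15, background = c(0, 0, 0),
                         image_size = 256L) {
  stopifnot(atom_radius_scale > 0, bond_radius > 0,
            length(background) == 3, all(background >= 0),
            all(background <= 255), image_size >= 32)
  stopifnot(all(vapply(atom_colors, function(cl)
    length(cl) == 3 && all(cl >= 0) && all(cl <= 255), logical(1))))
  structure(list(atom_colors = atom_colors,
                 atom_radius_scale = atom_radius_scale,
                 bond_radius = bond_radius,
                 background = background,
                 image_size = as.integer(image_size)),
            class = "render_style")
}

#' Enumerate snapshot rotation triples for an angle increment
#'
#' Per-axis angles are all multiples of `increment` in `[0, 360)`; the result
#' is the full Cartesian product over the x-, y- and z-axes in lexicographic
#' order `(rx, ry, rz)`, hence `m^3` rows where `m` is the per-axis multiple
#' count.
#'
#' @param increment Angle increment in degrees, in `(0, 360]`.
#' @return `data.frame` with columns `rx`, `ry`, `rz` (degrees).
#' @export
enumerate_angles <- function(increment) {
  if (!is.numeric(increment) || length(increment) != 1 || increment <= 0) {
    stop("increment must be a single positive number of degrees")
  }
  m <- floor((360 - 1e-9) / increment) + 1
  v <- increment * (seq_len(m) - 1)
  grid <- expand.grid(rz = v, ry = v, rx = v, KEEP.OUT.ATTRS = FALSE)
  data.frame(rx = grid$rx, ry = grid$ry, rz = grid$rz)
}

# Combined rotation: intrinsic x, then y, then z (degrees).
rotation_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

.light_dir <- c(-0.45, 0.55, 0.75) / sqrt(sum(c(-0.45, 0.55, 0.75)^2))
.ambient <- 0.35

element_color <- function(elements, atom_colors) {
  t(vapply(elements, function(e) {
    cl <- atom_colors[[e]]
    if (is.null(cl)) .cpk_default_color else cl
  }, numeric(3), USE.NAMES = FALSE)) / 255
}

element_radius <- function(elements, scale) {
  r <- .vdw_radii[elements]
  r[is.na(r)] <- .vdw_default
  unname(r) * scale
}

# Shade a set of pixels with a Lambert term; normal components as vectors.
.shade <- function(nx, ny, nz) {
  lam <- pmax(0, nx * .light_dir[1] + ny * .light_dir[2] + nz * .light_dir[3])
  .ambient + (1 - .ambient) * lam
}

#' Render one ball-and-stick snapshot
#'
#' Centers the conformer at its centroid, applies the intrinsic rotation
#' (about x, then y, then z), projects orthographically with a fit-to-frame
#' scale and a 10% margin, and rasterizes atoms as depth-sorted shaded spheres
#' and bonds as half-colored cylinders. A single fixed directional light in
#' camera space plus constant ambient term gives the shading, so the renderer
#' is fully deterministic: identical inputs produce bitwise identical rasters.
#'
#' @param conf A [conformer3d()] object with at least one atom.
#' @param rot Numeric rotation triple `c(rx, ry, rz)` in degrees.
#' @param style A [render_style()] object.
#' @return Numeric array `image_size x image_size x 3` with values in
#'   `[0, 1]`.
#' @export
render_snapshot <- function(conf, rot = c(0, 0, 0), style = render_style()) {
  stopifnot(inherits(conf, "conformer3d"), inherits(style, "render_style"))
  if (nrow(conf$atoms) < 1) stop("empty conformer")
  stopifnot(is.numeric(rot), length(rot) == 3)
  sz <- style$image_size
  margin <- 0.10

  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  R <- rotation_matrix(rot[1], rot[2], rot[3])
  p <- xyz %*% t(R)  # camera space: x right, y up, z toward viewer

  rad <- element_radius(conf$atoms$element, style$atom_radius_scale)
  reach <- pmax(rad, style$bond_radius)
  xmin <- min(p[, 1] - reach); xmax <- max(p[, 1] + reach)
  ymin <- min(p[, 2] - reach); ymax <- max(p[, 2] + reach)
  extent <- max(xmax - xmin, ymax - ymin, 1e-9)
  s <- sz * (1 - 2 * margin) / extent
  cx <- (xmin + xmax) / 2
  cy <- (ymin + ymax) / 2
  # pixel centers at (col - 0.5, row - 0.5); y axis flips (rows grow down)
  px <- sz / 2 + s * (p[, 1] - cx)
  py <- sz / 2 - s * (p[, 2] - cy)
  pz <- s * p[, 3]
  pr <- s * rad

  cols <- element_color(conf$atoms$element, style$atom_colors)
  img_r <- matrix(style$background[1] / 255, sz, sz)
  img_g <- matrix(style$background[2] / 255, sz, sz)
  img_b <- matrix(style$background[3] / 255, sz, sz)
  zbuf <- matrix(-Inf, sz, sz)

  paint <- function(rows, cols_idx, zz, keep, shade, rgb_col) {
    idx <- cbind(rows[keep], cols_idx[keep])
    zsel <- zz[keep]
    better <- zsel > zbuf[idx]
    if (!any(better)) return(invisible())
    idx <- idx[better, , drop = FALSE]
    sh <- shade[keep][better]
    zbuf[idx] <<- zsel[better]
    img_r[idx] <<- rgb_col[1] * sh
    img_g[idx] <<- rgb_col[2] * sh
    img_b[idx] <<- rgb_col[3] * sh
    invisible()
  }

  block <- function(x0, x1, y0, y1) {
    j0 <- max(1L, floor(x0 + 0.5)); j1 <- min(sz, ceiling(x1 + 0.5))
    i0 <- max(1L, floor(y0 + 0.5)); i1 <- min(sz, ceiling(y1 + 0.5))
    if (j0 > j1 || i0 > i1) return(NULL)
    list(i = i0:i1, j = j0:j1)
  }

  # bonds first is unnecessary: the z-buffer resolves order; draw bonds as
  # two half-cylinders colored by the nearer atom
  if (nrow(conf$bonds) > 0) {
    br <- s * style$bond_radius
    for (k in seq_len(nrow(conf$bonds))) {
      a1 <- conf$bonds$from[k]; a2 <- conf$bonds$to[k]
      ax <- px[a2] - px[a1]; ay <- py[a2] - py[a1]; az <- pz[a2] - pz[a1]
      len2 <- ax * ax + ay * ay
      if (len2 < 1e-12) next  # bond seen end-on: hidden by the atom spheres
      bb <- block(min(px[a1], px[a2]) - br, max(px[a1], px[a2]) + br,
                  min(py[a1], py[a2]) - br, max(py[a1], py[a2]) + br)
      if (is.null(bb)) next
      X <- matrix(bb$j - 0.5, length(bb$i), length(bb$j), byrow = TRUE)
      Y <- matrix(bb$i - 0.5, length(bb$i), length(bb$j))
      tt <- ((X - px[a1]) * ax + (Y - py[a1]) * ay) / len2
      tt <- pmin(1, pmax(0, tt))
      dx <- X - (px[a1] + tt * ax)
      dy <- Y - (py[a1] + tt * ay)
      d2 <- dx * dx + dy * dy
      inside <- d2 < br * br
      if (!any(inside)) next
      bulge <- sqrt(pmax(0, br * br - d2))
      zz <- pz[a1] + tt * az + bulge
      sh <- .shade(dx / br, -dy / br, bulge / br)
      rows <- matrix(bb$i, length(bb$i), length(bb$j))
      colsm <- matrix(bb$j, length(bb$i), length(bb$j), byrow = TRUE)
      for (half in 1:2) {
        keep <- inside & (if (half == 1) tt < 0.5 else tt >= 0.5)
        if (!any(keep)) next
        paint(rows, colsm, zz, keep, sh, cols[if (half == 1) a1 else a2, ])
      }
    }
  }

  for (a in seq_len(nrow(conf$atoms))) {
    bb <- block(px[a] - pr[a], px[a] + pr[a], py[a] - pr[a], py[a] + pr[a])
    if (is.null(bb)) next
    X <- matrix(bb$j - 0.5, length(bb$i), length(bb$j), byrow = TRUE)
    Y <- matrix(bb$i - 0.5, length(bb$i), length(bb$j))
    dx <- X - px[a]; dy <- Y - py[a]
    d2 <- dx * dx + dy * dy
    inside <- d2 < pr[a] * pr[a]
    if (!any(inside)) next
    hz <- sqrt(pmax(0, pr[a]^2 - d2))
    zz <- pz[a] + hz
    sh <- .shade(dx / pr[a], -dy / pr[a], hz / pr[a])
    rows <- matrix(bb$i, length(bb$i), length(bb$j))
    colsm <- matrix(bb$j, length(bb$i), length(bb$j), byrow = TRUE)
    paint(rows, colsm, zz, inside, sh, cols[a, ])
  }

  img <- array(0, c(sz, sz, 3))
  img[, , 1] <- img_r; img[, , 2] <- img_g; img[, , 3] <- img_b
  pmax(pmin(img, 1), 0)
}

fmt_angle <- function(x) {
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 4))
}

#' Capture the full snapshot set of a molecule
#'
#' Renders one PNG per rotation triple of [enumerate_angles()] into `outdir`.
#' Filenames encode the molecule id and rotation as
#' `{id}_{rx}_{ry}_{rz}.png`. Re-running overwrites files in place with
#' identical bytes.
#'
#' @param conf A [conformer3d()] object.
#' @param increment Angle increment in degrees, in `(0, 360]`.
#' @param style A [render_style()] object.
#' @param outdir Output directory (created if absent).
#' @param molecule_id Identifier used in filenames; defaults to `conf$id`.
#' @return A list of class `snapshot_set` with fields `molecule_id`,
#'   `increment` and `items` (`data.frame` of `rx`, `ry`, `rz`, `path`).
#' @export
snapshot_molecule <- function(conf, increment, style = render_style(),
                              outdir, molecule_id = conf$id) {
  angles <- enumerate_angles(increment)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create outdir: ", outdir)
  }
  if (file.access(outdir, mode = 2) != 0) {
    stop("outdir is not writable: ", outdir)
  }
  paths <- character(nrow(angles))
  for (i in seq_len(nrow(angles))) {
    img <- render_snapshot(conf, c(angles$rx[i], angles$ry[i], angles$rz[i]),
                           style)
    paths[i] <- file.path(outdir, paste0(
      molecule_id, "_", fmt_angle(angles$rx[i]), "_", fmt_angle(angles$ry[i]),
      "_", fmt_angle(angles$rz[i]), ".png"))
    png::writePNG(img, paths[i])
  }
  structure(list(molecule_id = molecule_id, increment = increment,
                 items = cbind(angles, path = paths)),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat("<snapshot_set> ", x$molecule_id, ": ", nrow(x$items),
      " snapshots at increment ", x$increment, "°\n", sep = "")
  invisible(x)
}
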