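#' Phantom specification
#'
#' Parameters of the synthetic brain phantom: an ellipsoidal brain of
#' uniform tissue intensity with a central CSF-bright ventricle block,
#' populated with CSF-bright perivascular-space (PVS) structures that
#' appear as in-plane linear segments (tubes) or through-plane dots on
#' axial slices, plus optional curvilinear sulcus-like arcs hugging the
#' brain boundary and larger lacune-like blobs as confounders. A fraction
#' of the PVSs can be rendered at reduced contrast to emulate
#' low-signal PVSs that segmenters tend to miss.
#'
#' Default voxel geometry matches high-resolution axial T2 at 3T
#' (0.69 x 0.69 mm in plane, 2 mm slices) with a 320 x 320 in-plane
#' matrix.
#'
#' @param grid_shape Integer 3-vector of voxel counts (x, y, z = slices).
#' @param voxel_size_mm Voxel size in mm.
#' @param n_tubes Number of in-plane linear PVSs.
#' @param n_dots Number of through-plane dot-like PVSs.
#' @param tube_length_mm Length range (mm) of in-plane PVSs.
#' @param dot_length_mm Through-plane extent range (mm) of dot PVSs.
#' @param pvs_radius_mm PVS radius range (mm).
#' @param tissue_mean,csf_mean,pvs_mean Intensities (arbitrary units);
#'   PVSs are CSF-like, so `pvs_mean` is close to `csf_mean` and both
#'   exceed `tissue_mean`.
#' @param n_sulci Number of sulcus-like bright arcs on the brain boundary.
#' @param n_lacunes Number of lacune-like bright blobs (larger than the
#'   PVS radius range).
#' @param low_signal_fraction Fraction of PVSs rendered at reduced
#'   contrast (intensity strictly between tissue and `pvs_mean`).
#' @param noise_sigma Noise scale (intensity units).
#' @param noise_model `"rician"` (MR magnitude noise, default) or
#'   `"gaussian"`.
#' @param min_separation_mm Minimum spacing between distinct PVS
#'   structures (between capsule surfaces and between centres).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(320L, 320L, 64L),
                         voxel_size_mm = c(0.69, 0.69, 2),
                         n_tubes = 25L, n_dots = 35L,
                         tube_length_mm = c(5, 25),
                         dot_length_mm = c(2, 6),
                         pvs_radius_mm = c(0.35, 1),
                         tissue_mean = 100, csf_mean = 200, pvs_mean = 190,
                         n_sulci = 8L, n_lacunes = 2L,
                         low_signal_fraction = 0.15,
                         noise_sigma = 4,
                         noise_model = c("rician", "gaussian"),
                         min_separation_mm = 4, seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               n_tubes = as.integer(n_tubes), n_dots = as.integer(n_dots),
               tube_length_mm = tube_length_mm,
               dot_length_mm = dot_length_mm,
               pvs_radius_mm = pvs_radius_mm,
               tissue_mean = tissue_mean, csf_mean = csf_mean,
               pvs_mean = pvs_mean,
               n_sulci = as.integer(n_sulci),
               n_lacunes = as.integer(n_lacunes),
               low_signal_fraction = low_signal_fraction,
               noise_sigma = noise_sigma, noise_model = noise_model,
               min_separation_mm = min_separation_mm,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(grid_shape <= 0)) stop("grid_shape must be positive")
    if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
    if (n_tubes < 0 || n_dots < 0 || n_sulci < 0 || n_lacunes < 0) {
      stop("structure counts must be >= 0")
    }
    if (any(pvs_radius_mm <= 0) || any(tube_length_mm <= 0) ||
        any(dot_length_mm <= 0)) {
      stop("radius and length ranges must be positive")
    }
    if (pvs_mean <= tissue_mean) stop("pvs_mean must exceed tissue_mean")
    if (csf_mean <= tissue_mean) stop("csf_mean must exceed tissue_mean")
    if (low_signal_fraction < 0 || low_signal_fraction > 1) {
      stop("low_signal_fraction must be in [0, 1]")
    }
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (min_separation_mm < 0) stop("min_separation_mm must be >= 0")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d x %d voxels (%.2f x %.2f x %.2f mm), %d tubes + %d dots,\n  %d sulci, %d lacunes, low-signal fraction %.2f, %s noise sigma %.1f, seed %d\n",
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    x$n_tubes, x$n_dots, x$n_sulci, x$n_lacunes, x$low_signal_fraction,
    x$noise_model, x$noise_sigma, x$seed))
  invisible(x)
}

# Geometry of the schematic anatomy in mm. Voxel (i, j, k) has its centre
# at ((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz).
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  extent <- d * vs
  centre <- extent / 2
  semi <- 0.45 * extent
  vent_half <- c(0.15, 0.30, 0.22) * semi
  vent_centre <- centre + c(0, 0, -0.1 * semi[3])
  zc <- (seq_len(d[3]) - 0.5) * vs[3]
  vent_slices <- which(abs(zc - vent_centre[3]) <= vent_half[3])
  if (length(vent_slices) < 1L || max(vent_slices) >= d[3]) {
    stop("grid too small to contain the brain and ventricle: ",
         "increase grid_shape (need slices above the ventricle top)")
  }
  list(dims = d, vs = vs, centre = centre, semi = semi,
       vent_centre = vent_centre, vent_half = vent_half,
       ventricle_top_index = max(vent_slices),
       bg_slice_index = vent_slices[which.min(abs(zc[vent_slices] -
                                                    vent_centre[3]))])
}

# mm coordinates of all voxel centres along each axis
axis_mm <- function(geom) {
  lapply(1:3, function(a) (seq_len(geom$dims[a]) - 0.5) * geom$vs[a])
}

#' Generate the brain background volume
#'
#' Ellipsoidal brain region at `tissue_mean` with a central CSF-bright
#' ventricle block at `csf_mean`; exterior at zero. Purely deterministic
#' given the spec. The returned volume carries the anatomical landmark
#' indices as attributes `ventricle_top_index` and `bg_slice_index`.
#'
#' @param spec A [phantom_spec()].
#' @return A [pvs_volume()] with landmark attributes.
#' @export
make_brain_background <- function(spec) {
  geom <- phantom_geometry(spec)
  ax <- axis_mm(geom)
  d <- geom$dims
  ex <- (ax[[1]] - geom$centre[1]) / geom$semi[1]
  ey <- (ax[[2]] - geom$centre[2]) / geom$semi[2]
  ez <- (ax[[3]] - geom$centre[3]) / geom$semi[3]
  rho2 <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`)
  brain <- rho2 <= 1
  vol <- array(0, d)
  vol[brain] <- spec$tissue_mean
  vx <- abs(ax[[1]] - geom$vent_centre[1]) <= geom$vent_half[1]
  vy <- abs(ax[[2]] - geom$vent_centre[2]) <= geom$vent_half[2]
  vz <- abs(ax[[3]] - geom$vent_centre[3]) <= geom$vent_half[3]
  vent <- outer(outer(vx, vy, `&`), vz, `&`) & brain
  vol[vent] <- spec$csf_mean
  out <- pvs_volume(vol, voxel_size_mm = geom$vs, subject_id = "phantom")
  attr(out, "ventricle_top_index") <- geom$ventricle_top_index
  attr(out, "bg_slice_index") <- geom$bg_slice_index
  out
}

# Shortest distance between two 3D segments (p0,p1) and (q0,q1).
seg_seg_dist <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  sN <- D; sD <- D; tN <- D; tD <- D
  if (D < 1e-12) { sN <- 0; sD <- 1; tN <- e; tD <- cc }
  else {
    sN <- b * e - cc * d; tN <- a * e - b * d
    if (sN < 0) { sN <- 0; tN <- e; tD <- cc }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- cc }
  }
  if (tN < 0) {
    tN <- 0
    if (-d < 0) sN <- 0 else if (-d > a) sN <- sD else { sN <- -d; sD <- a }
  } else if (tN > tD) {
    tN <- tD
    if ((-d + b) < 0) sN <- 0
    else if ((-d + b) > a) sN <- sD
    else { sN <- -d + b; sD <- a }
  }
  s <- if (abs(sD) < 1e-12) 0 else sN / sD
  t <- if (abs(tD) < 1e-12) 0 else tN / tD
  sqrt(sum((w + s * u - t * v)^2))
}

structure_endpoints <- function(st) {
  ctr <- c(st$cx, st$cy, st$cz)
  dir <- c(st$dx, st$dy, st$dz)
  list(p0 = ctr - dir * st$length_mm / 2, p1 = ctr + dir * st$length_mm / 2)
}

#' Sample PVS structure placements
#'
#' Places `n_tubes` in-plane segments (random azimuth, zero z component:
#' they appear as lines on axial slices) and `n_dots` through-plane
#' segments (direction along z: they appear as dots) inside the brain
#' ellipsoid, outside the ventricle, respecting the minimum separation
#' both between centres and between capsule surfaces. Uses the current
#' RNG stream.
#'
#' @param spec A [phantom_spec()].
#' @return `data.frame` (the structure table) with columns `type`, `cx`,
#'   `cy`, `cz` (centre, mm), `dx`, `dy`, `dz` (unit direction),
#'   `length_mm`, `radius_mm`, `low_signal`, `contrast`.
#' @export
sample_pvs_structures <- function(spec) {
  geom <- phantom_geometry(spec)
  n <- spec$n_tubes + spec$n_dots
  cols <- c("cx", "cy", "cz", "dx", "dy", "dz", "length_mm", "radius_mm")
  tab <- data.frame(type = character(0))
  for (col in cols) tab[[col]] <- numeric(0)
  if (n == 0L) {
    tab$low_signal <- logical(0)
    tab$contrast <- numeric(0)
    return(tab)
  }
  types <- c(rep("tube", spec$n_tubes), rep("dot", spec$n_dots))
  placed <- list()
  runif_rng <- function(rg) stats::runif(1, rg[1], rg[2])
  for (k in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(400L)) {
      radius <- runif_rng(spec$pvs_radius_mm)
      if (types[k] == "tube") {
        theta <- stats::runif(1, 0, 2 * pi)
        dir <- c(cos(theta), sin(theta), 0)
        len <- runif_rng(spec$tube_length_mm)
      } else {
        dir <- c(0, 0, 1)
        len <- runif_rng(spec$dot_length_mm)
      }
      ctr <- geom$centre + (stats::runif(3, -1, 1) * geom$semi)
      cand <- list(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                   dx = dir[1], dy = dir[2], dz = dir[3],
                   length_mm = len, radius_mm = radius)
      if (!placement_ok(cand, placed, spec, geom)) next
      placed[[k]] <- c(cand, list(type = types[k]))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place PVS structure ", k, " of ", n,
           " at min_separation_mm = ", spec$min_separation_mm,
           " after bounded retries; achieved ", k - 1L,
           " structures (reduce counts or separation)")
    }
  }
  tab <- do.call(rbind, lapply(placed, function(p) {
    data.frame(type = p$type, cx = p$cx, cy = p$cy, cz = p$cz,
               dx = p$dx, dy = p$dy, dz = p$dz,
               length_mm = p$length_mm, radius_mm = p$radius_mm)
  }))
  n_low <- round(spec$low_signal_fraction * n)
  low <- rep(FALSE, n)
  if (n_low > 0L) low[sample.int(n, n_low)] <- TRUE
  tab$low_signal <- low
  # low-signal PVSs sit 45% of the way from tissue to full PVS intensity
  tab$contrast <- ifelse(low,
                         spec$tissue_mean + 0.45 * (spec$pvs_mean -
                                                      spec$tissue_mean),
                         spec$pvs_mean)
  tab
}

placement_ok <- function(cand, placed, spec, geom) {
  ctr <- c(cand$cx, cand$cy, cand$cz)
  dir <- c(cand$dx, cand$dy, cand$dz)
  p0 <- ctr - dir * cand$length_mm / 2
  p1 <- ctr + dir * cand$length_mm / 2
  # whole capsule inside a shrunken brain ellipsoid, clear of the
  # boundary band where sulcus confounders live
  erad <- function(p) sqrt(sum(((p - geom$centre) / geom$semi)^2))
  margin <- cand$radius_mm / min(geom$semi)
  if (erad(p0) + margin > 0.85 || erad(p1) + margin > 0.85 ||
      erad(ctr) + margin > 0.85) {
    return(FALSE)
  }
  # clear of the ventricle block (expanded by the radius + 1 mm)
  ex <- geom$vent_half + cand$radius_mm + 1
  lo <- pmin(p0, p1) - cand$radius_mm
  hi <- pmax(p0, p1) + cand$radius_mm
  if (all(hi >= geom$vent_centre - ex) && all(lo <= geom$vent_centre + ex)) {
    return(FALSE)
  }
  for (q in placed) {
    if (sqrt(sum((ctr - c(q$cx, q$cy, q$cz))^2)) < spec$min_separation_mm) {
      return(FALSE)
    }
    qe <- structure_endpoints(q)
    if (seg_seg_dist(p0, p1, qe$p0, qe$p1) <
        cand$radius_mm + q$radius_mm + spec$min_separation_mm / 2) {
      return(FALSE)
    }
  }
  TRUE
}

# Voxel indices (n x 3 integer matrix) covered by one capsule.
rasterize_one <- function(st, geom) {
  ep <- structure_endpoints(st)
  vs <- geom$vs
  d <- geom$dims
  lo <- pmin(ep$p0, ep$p1) - st$radius_mm
  hi <- pmax(ep$p0, ep$p1) + st$radius_mm
  i0 <- pmax(1L, floor(lo / vs + 0.5))
  i1 <- pmin(d, ceiling(hi / vs + 0.5))
  if (any(i0 > i1)) {
    idx <- matrix(0L, 0L, 3L)
  } else {
    g <- expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2], k = i0[3]:i1[3])
    p <- cbind((g$i - 0.5) * vs[1], (g$j - 0.5) * vs[2], (g$k - 0.5) * vs[3])
    u <- ep$p1 - ep$p0
    len2 <- sum(u * u)
    w <- sweep(p, 2, ep$p0)
    tt <- if (len2 < 1e-12) rep(0, nrow(p)) else {
      pmin(1, pmax(0, (w %*% u) / len2))
    }
    closest <- outer(as.vector(tt), u)
    dist <- sqrt(rowSums((w - closest)^2))
    keep <- dist <= st$radius_mm
    idx <- as.matrix(g[keep, , drop = FALSE])
  }
  # guaranteed support: the centre voxel is always painted so thin PVSs
  # (radius below the voxel size) never vanish under anisotropic sampling
  ctr_vox <- pmin(d, pmax(1L, ceiling(c(st$cx, st$cy, st$cz) / vs)))
  idx <- rbind(idx, matrix(as.integer(ctr_vox), 1L, 3L))
  storage.mode(idx) <- "integer"
  unique(idx)
}

#' Rasterize PVS structures into a binary mask
#'
#' Each structure is painted as a capsule (cylinder with hemispherical
#' caps) of its radius, honouring the anisotropic voxel size; the mask is
#' the union. The centre voxel of every structure is always painted, so a
#' requested structure can never vanish even when its radius is below the
#' voxel size.
#'
#' @param structures Structure table from [sample_pvs_structures()].
#' @param spec A [phantom_spec()] supplying the grid geometry.
#' @return 3D binary array.
#' @export
rasterize_structures <- function(structures, spec) {
  geom <- phantom_geometry(spec)
  mask <- array(0L, geom$dims)
  if (nrow(structures) > 0L) {
    for (k in seq_len(nrow(structures))) {
      idx <- rasterize_one(structures[k, ], geom)
      mask[idx] <- 1L
    }
  }
  mask
}

#' Render the phantom volume
#'
#' Paints each PVS structure at its assigned contrast (full `pvs_mean`, or
#' interpolated toward `tissue_mean` for low-signal structures), adds
#' sulcus-like bright arcs in a band hugging the brain boundary and
#' lacune-like bright blobs away from the PVSs, then applies noise last
#' (Rician by default: the magnitude of a complex Gaussian-perturbed
#' signal). Consumes the current RNG stream.
#'
#' @param background Volume from [make_brain_background()].
#' @param mask Binary PVS mask from [rasterize_structures()].
#' @param structures Structure table.
#' @param spec A [phantom_spec()].
#' @return A [pvs_volume()].
#' @export
render_phantom <- function(background, mask, structures, spec) {
  geom <- phantom_geometry(spec)
  vol <- background$data
  if (nrow(structures) > 0L) {
    for (k in seq_len(nrow(structures))) {
      idx <- rasterize_one(structures[k, ], geom)
      vol[idx] <- structures$contrast[k]
    }
  }
  if (spec$n_sulci > 0L) vol <- add_sulci(vol, mask, spec, geom)
  if (spec$n_lacunes > 0L) vol <- add_lacunes(vol, mask, structures, spec,
                                              geom)
  if (spec$noise_sigma > 0) {
    nvox <- length(vol)
    if (spec$noise_model == "gaussian") {
      vol <- vol + spec$noise_sigma * stats::rnorm(nvox)
    } else {
      vol <- sqrt((vol + spec$noise_sigma * stats::rnorm(nvox))^2 +
                    (spec$noise_sigma * stats::rnorm(nvox))^2)
    }
    vol <- array(vol, geom$dims)
  }
  pvs_volume(vol, voxel_size_mm = geom$vs, subject_id = background$subject_id)
}

# Curvilinear CSF-bright arcs in the elliptic band just inside the brain
# boundary, each spanning one or two adjacent slices.
add_sulci <- function(vol, mask, spec, geom) {
  ax <- axis_mm(geom)
  d <- geom$dims
  zc <- ax[[3]]
  usable <- which(abs(zc - geom$centre[3]) < 0.75 * geom$semi[3])
  for (s in seq_len(spec$n_sulci)) {
    k <- sample(usable, 1L)
    theta0 <- stats::runif(1, 0, 2 * pi)
    width <- stats::runif(1, pi / 9, pi / 3)
    span <- sample(1:2, 1L)
    zfrac <- (zc[k] - geom$centre[3]) / geom$semi[3]
    shrink <- sqrt(max(0.05, 1 - zfrac^2))
    az <- geom$semi[1] * shrink
    bz <- geom$semi[2] * shrink
    xs <- ax[[1]] - geom$centre[1]
    ys <- ax[[2]] - geom$centre[2]
    rho <- sqrt(outer((xs / az)^2, (ys / bz)^2, `+`))
    ang <- atan2(outer(rep(1, d[1]), ys), outer(xs, rep(1, d[2])))
    dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
    band <- rho >= 0.88 & rho <= 0.95 & dang <= width / 2
    for (kk in k:min(d[3], k + span - 1L)) {
      sl <- vol[, , kk]
      keep <- band & mask[, , kk] == 0L & sl > 0
      sl[keep] <- spec$csf_mean
      vol[, , kk] <- sl
    }
  }
  vol
}

# Bright ellipsoidal blobs, larger than the PVS radius range, away from
# the PVS structures.
add_lacunes <- function(vol, mask, structures, spec, geom) {
  for (s in seq_len(spec$n_lacunes)) {
    for (attempt in seq_len(200L)) {
      radius <- stats::runif(1, 2.5, 4)
      ctr <- geom$centre + stats::runif(3, -1, 1) * geom$semi
      erad <- sqrt(sum(((ctr - geom$centre) / geom$semi)^2))
      if (erad > 0.8) next
      ex <- geom$vent_half + radius + 1
      if (all(abs(ctr - geom$vent_centre) <= ex)) next
      if (nrow(structures) > 0L) {
        clear <- TRUE
        for (k in seq_len(nrow(structures))) {
          qe <- structure_endpoints(structures[k, ])
          if (seg_seg_dist(ctr, ctr, qe$p0, qe$p1) <
              radius + structures$radius_mm[k] + spec$min_separation_mm / 2) {
            clear <- FALSE
            break
          }
        }
        if (!clear) next
      }
      st <- list(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 dx = 0, dy = 0, dz = 1, length_mm = 1e-6,
                 radius_mm = radius)
      idx <- rasterize_one(st, geom)
      keep <- mask[idx] == 0L
      vol[idx[keep, , drop = FALSE]] <- spec$csf_mean
      break
    }
  }
  vol
}

#' Generate one phantom subject
#'
#' Seeds the RNG from `spec$seed`, samples and rasterizes the PVS
#' structures, renders the volume, and assembles the ground truth:
#' the binary mask, per-slice true counts (connected components under
#' 8-connectivity, slice by slice), the anatomical landmark indices and
#' the structure table.
#'
#' The centrum-semiovale counting slice is placed 1 cm above the
#' uppermost ventricle slice: `ventricle_top_index +
#' ceiling(10 / slice_thickness_mm)`.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Identifier for the generated subject.
#' @return List of class `phantom_subject` with elements `volume`
#'   (a [pvs_volume()]), `truth` (class `phantom_truth`: `mask`,
#'   `per_slice_counts`, `bg_slice_index`, `cso_slice_index`,
#'   `ventricle_top_index`, `structure_table`) and `spec`.
#' @export
phantom_subject <- function(spec, subject_id = "phantom") {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  geom <- phantom_geometry(spec)
  background <- make_brain_background(spec)
  background$subject_id <- subject_id
  structures <- sample_pvs_structures(spec)
  mask <- rasterize_structures(structures, spec)
  volume <- render_phantom(background, mask, structures, spec)
  counts <- vapply(seq_len(geom$dims[3]), function(k) {
    count_on_slice(mask[, , k], connectivity = 8)
  }, integer(1))
  cso <- geom$ventricle_top_index +
    as.integer(ceiling(10 / spec$voxel_size_mm[3]))
  truth <- structure(list(
    mask = mask, per_slice_counts = counts,
    bg_slice_index = geom$bg_slice_index,
    cso_slice_index = cso,
    ventricle_top_index = geom$ventricle_top_index,
    structure_table = structures
  ), class = "phantom_truth")
  structure(list(volume = volume, truth = truth, spec = spec,
                 subject_id = subject_id),
            class = "phantom_subject")
}

#' Generate a phantom dataset
#'
#' Subject `k` is generated from derived seed `seed + k - 1`, so a dataset
#' can be extended without reshuffling earlier subjects. Synthetic ages
#' are drawn uniformly over `age_range` (default 42-79 years, the typical
#' span of a Parkinson's disease cohort) from the master seed, giving the
#' fairly uniform age distribution the fold-balancing protocol expects.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param spec A [phantom_spec()] shared by all subjects (its `seed` field
#'   is overridden per subject).
#' @param seed Master seed; defaults to `spec$seed`.
#' @param age_range Inclusive integer age range.
#' @return List of class `phantom_dataset`; each element is a
#'   `phantom_subject` with added `age`.
#' @export
phantom_dataset <- function(n_subjects, spec = phantom_spec(),
                            seed = spec$seed, age_range = c(42, 79)) {
  stopifnot(n_subjects >= 1L)
  set.seed(seed)
  ages <- sample(seq(age_range[1], age_range[2]), n_subjects, replace = TRUE)
  subjects <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    sp <- spec
    sp$seed <- as.integer(seed + k - 1L)
    sub <- phantom_subject(sp, subject_id = sprintf("sub-%03d", k))
    sub$age <- ages[k]
    subjects[[k]] <- sub
  }
  structure(subjects, class = "phantom_dataset")
}

#' Write a phantom dataset to disk
#'
#' Writes paired image/label NIfTI files (image float, label unsigned
#' 8-bit in `{0, 1}`) with voxel size in the header, one JSON truth
#' sidecar per subject (per-slice counts, landmark indices, structure
#' table, age) and a dataset manifest.
#'
#' @param dataset A [phantom_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_subjects = length(dataset), subjects = list())
  for (sub in dataset) {
    id <- sub$subject_id
    img <- file.path(dir, paste0(id, "_T2w.nii.gz"))
    lab <- file.path(dir, paste0(id, "_mask.nii.gz"))
    side <- file.path(dir, paste0(id, "_truth.json"))
    write_volume(sub$volume, img)
    write_volume(sub$truth$mask, lab, mask = TRUE,
                 voxel_size_mm = sub$volume$voxel_size_mm)
    tr <- sub$truth
    jsonlite::write_json(list(
      subject_id = id, age = sub$age,
      per_slice_counts = tr$per_slice_counts,
      bg_slice_index = tr$bg_slice_index,
      cso_slice_index = tr$cso_slice_index,
      ventricle_top_index = tr$ventricle_top_index,
      structure_table = tr$structure_table,
      seed = sub$spec$seed
    ), side, auto_unbox = TRUE, digits = NA)
    manifest$subjects[[length(manifest$subjects) + 1L]] <-
      list(subject_id = id, image = basename(img), label = basename(lab),
           truth = basename(side), age = sub$age)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
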