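#' Monte Carlo configuration
#'
#' @param electrons_per_pixel Trajectories per beam position (>= 1).
#' @param rng_seed Integer seed; identical seed and config give identical
#'   images regardless of pixel evaluation order (each pixel owns a stream
#'   derived from `(seed, pixel index)`).
#' @param max_events Safety cap on real scattering events per trajectory.
#' @param channel Scattering channels in transport: `"both"` or `"elastic"`.
#' @param delta_e_ev,relativistic,theta_max_mrad Physics options, as in
#'   [build_scattering_table()].
#' @return An `lv_mc_config`.
#' @export
mc_config <- function(electrons_per_pixel = 1000, rng_seed = 1,
                      max_events = 1000,
                      channel = c("both", "elastic"),
                      delta_e_ev = 20, relativistic = FALSE,
                      theta_max_mrad = 500 * pi) {
  channel <- match.arg(channel)
  if (electrons_per_pixel < 1) abort("`electrons_per_pixel` must be >= 1.")
  structure(list(electrons_per_pixel = as.integer(electrons_per_pixel),
                 rng_seed = as.integer(rng_seed),
                 max_events = as.integer(max_events), channel = channel,
                 delta_e_ev = delta_e_ev, relativistic = relativistic,
                 theta_max_mrad = theta_max_mrad),
            class = "lv_mc_config")
}

# deterministic 31-bit stream seed per (seed, counter)
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(counter) * 30103 + 1) %%
               2147483647)
}

#' Sample scattering events from a table
#'
#' Free paths are exponential with the total mean free path; polar
#' deflections are drawn from the combined Lenz angular kernel by
#' inverse-transform on the tabulated CDF; azimuths are uniform.
#'
#' @param n Number of events.
#' @param table An `lv_scattering_table`.
#' @return Tibble with `free_path` (nm), `polar_mrad`, `azimuth_rad`.
#' @export
sample_scatter <- function(n, table) {
  stopifnot(inherits(table, "lv_scattering_table"))
  tibble(
    free_path = rexp(n, 1 / table$lambda_total),
    polar_mrad = sample_polar(n, table),
    azimuth_rad = runif(n, 0, 2 * pi)
  )
}

sample_polar <- function(n, table) {
  approx(table$angle_cdf, table$angle_grid, runif(n), ties = "ordered")$y
}

# rotate unit directions (ux,uy,uz) by polar angle th (rad) about a uniform
# azimuth ph; standard MC direction update
rotate_direction <- function(ux, uy, uz, th, ph) {
  ct <- cos(th); st <- sin(th); cp <- cos(ph); sp <- sin(ph)
  den <- sqrt(pmax(1 - uz^2, 0))
  safe <- den > 1e-9
  nx <- ifelse(safe, st * (cp * uz * ux - sp * uy) / pmax(den, 1e-12) + ct * ux,
               st * cp * sign_z(uz))
  ny <- ifelse(safe, st * (cp * uz * uy + sp * ux) / pmax(den, 1e-12) + ct * uy,
               st * sp * sign_z(uz))
  nz <- ifelse(safe, -st * cp * den + ct * uz, ct * uz)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  list(x = nx / nrm, y = ny / nrm, z = nz / nrm)
}

sign_z <- function(z) ifelse(z >= 0, 1, -1)

# Woodcock (delta-tracking) transport of a batch of electrons entering at
# (x, y, ztop) moving along -z. Returns per-electron outcome and exit angle.
trace_batch <- function(scene, x0, y0, tables, sigma_max, config) {
  n <- length(x0)
  ztop <- scene_top(scene)
  x <- x0; y <- y0; z <- rep(ztop + 1e-6, n)
  ux <- rep(0, n); uy <- rep(0, n); uz <- rep(-1, n)
  events <- integer(n)
  status <- rep.int(0L, n)  # 0 in flight, 1 transmitted, 2 backscattered, 3 capped
  exit_polar <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  sig_by_index <- vapply(seq_along(tables), function(i)
    1 / tables[[i]]$lambda_total, numeric(1))
  steps <- 0L
  max_steps <- config$max_events * 20L
  while (any(alive) && steps < max_steps) {
    steps <- steps + 1L
    i <- which(alive)
    s <- rexp(length(i), sigma_max)
    x[i] <- x[i] + s * ux[i]
    y[i] <- y[i] + s * uy[i]
    z[i] <- z[i] + s * uz[i]
    below <- z[i] <= 0
    above <- z[i] >= ztop + 1e-3 & uz[i] > 0
    done_t <- i[below]
    if (length(done_t)) {
      status[done_t] <- 1L
      exit_polar[done_t] <- acos(pmin(1, pmax(-1, -uz[done_t]))) * 1e3
      alive[done_t] <- FALSE
    }
    done_b <- i[above & !below]
    if (length(done_b)) {
      status[done_b] <- 2L
      alive[done_b] <- FALSE
    }
    j <- i[!below & !(above & !below)]
    if (!length(j)) next
    mi <- material_index_at(scene, x[j], y[j], z[j])
    # map material index to table index (support = 1, primitive i = i + 1)
    ti <- mi + 2L
    sig_here <- ifelse(mi < 0L, 0, sig_by_index[pmax(ti - 1L, 1L)])
    hit <- runif(length(j)) < sig_here / sigma_max
    k <- j[hit]
    if (length(k)) {
      tk <- (material_index_at(scene, x[k], y[k], z[k]) + 1L)
      th <- numeric(length(k)); idx <- seq_along(k)
      for (t_id in unique(tk)) {
        sel <- idx[tk == t_id]
        th[sel] <- sample_polar(length(sel), tables[[t_id]]) * 1e-3
      }
      ph <- runif(length(k), 0, 2 * pi)
      rot <- rotate_direction(ux[k], uy[k], uz[k], th, ph)
      ux[k] <- rot$x; uy[k] <- rot$y; uz[k] <- rot$z
      events[k] <- events[k] + 1L
      capped <- k[events[k] >= config$max_events]
      if (length(capped)) {
        status[capped] <- 3L
        alive[capped] <- FALSE
      }
    }
  }
  status[alive] <- 3L  # ran out of steps: treat as capped
  list(status = status, exit_polar_mrad = exit_polar, events = events)
}

scene_tables <- function(scene, beam, detector, config) {
  mats <- c(list(scene$support), lapply(scene$primitives, function(p) p$material))
  lapply(mats, build_scattering_table, beam = beam, detector = detector,
         channel = config$channel, delta_e_ev = config$delta_e_ev,
         relativistic = config$relativistic,
         theta_max_mrad = config$theta_max_mrad)
}

#' Trace electrons through a scene at one beam position
#'
#' Traces `n` trajectories entering at `(x, y)` at the top of the scene
#' moving along -z, with Woodcock (delta) tracking between scattering events
#' sampled from the local material's Lenz table. Vacuum does not scatter.
#'
#' @param scene An [specimen_scene()].
#' @param x,y Beam position, nm.
#' @param beam Beam condition or energy, keV.
#' @param detector An [annular_detector()] (used for the summary counts).
#' @param config An [mc_config()].
#' @param n Number of trajectories (default from `config`).
#' @return Tibble with per-electron `status` (`"transmitted"`,
#'   `"backscattered"`, `"capped"`) and `exit_polar_mrad` (NA unless
#'   transmitted), plus attribute `summary` (counts in/out of the annulus).
#' @export
trace_electron <- function(scene, x = 0, y = 0, beam = 30,
                           detector = annular_detector(15, 55),
                           config = mc_config(), n = NULL) {
  n <- n %||% config$electrons_per_pixel
  tables <- scene_tables(scene, beam, detector, config)
  sigma_max <- max(vapply(tables, function(t) 1 / t$lambda_total, numeric(1)))
  set.seed(derive_seed(config$rng_seed, 0L))
  res <- trace_batch(scene, rep(x, n), rep(y, n), tables, sigma_max, config)
  out <- tibble(
    status = c("in_flight", "transmitted", "backscattered", "capped")[res$status + 1L],
    exit_polar_mrad = res$exit_polar_mrad,
    events = res$events
  )
  detected <- !is.na(res$exit_polar_mrad) &
    res$exit_polar_mrad >= detector$inner_mrad &
    res$exit_polar_mrad <= detector$outer_mrad
  attr(out, "summary") <- tibble(
    n = n, detected = sum(detected),
    transmitted_outside = sum(res$status == 1L) - sum(detected),
    backscattered = sum(res$status == 2L), capped = sum(res$status == 3L)
  )
  out
}

#' Monte Carlo dark-field image
#'
#' Per pixel, `electrons_per_pixel` trajectories enter at the pixel's beam
#' position; the pixel value is the count of electrons exiting the bottom
#' plane with polar angle inside the detector annulus. Each pixel draws from
#' its own RNG stream derived from `(rng_seed, pixel index)`, so the image is
#' independent of evaluation order. Capped trajectories are excluded from
#' scoring but tallied.
#'
#' @param scene An [specimen_scene()].
#' @param beam Beam condition or energy in keV.
#' @param detector An [annular_detector()].
#' @param config An [mc_config()].
#' @param raster An [image_raster()]; must lie inside the scene bounds.
#' @return An [stem_image()] (channel `"DF"`) whose pixels are detected
#'   counts; metadata records the config, plus matrices of backscatter and
#'   cap tallies in `provenance`.
#' @export
simulate_df_image <- function(scene, beam = 30,
                              detector = annular_detector(15, 55),
                              config = mc_config(),
                              raster = image_raster(64, 48, 1)) {
  co <- raster_coords(raster)
  b <- scene$bounds
  if (min(co$x) < b[1] || max(co$x) > b[2] ||
      min(co$y) < b[3] || max(co$y) > b[4]) {
    abort("Raster window extends outside the scene bounds.")
  }
  tables <- scene_tables(scene, beam, detector, config)
  sigma_max <- max(vapply(tables, function(t) 1 / t$lambda_total, numeric(1)))
  counts <- matrix(0L, raster$ny, raster$nx)
  backsc <- matrix(0L, raster$ny, raster$nx)
  capped <- matrix(0L, raster$ny, raster$nx)
  npx <- config$electrons_per_pixel
  for (p in seq_len(raster$ny * raster$nx)) {
    set.seed(derive_seed(config$rng_seed, p))
    res <- trace_batch(scene, rep(co$x[p], npx), rep(co$y[p], npx),
                       tables, sigma_max, config)
    det <- !is.na(res$exit_polar_mrad) &
      res$exit_polar_mrad >= detector$inner_mrad &
      res$exit_polar_mrad <= detector$outer_mrad
    counts[p] <- sum(det)
    backsc[p] <- sum(res$status == 2L)
    capped[p] <- sum(res$status == 3L)
  }
  stem_image(counts, pixel_size = raster$pixel_size, channel = "DF",
             provenance = list(kind = "mc", seed = config$rng_seed,
                               electrons_per_pixel = npx,
                               channel = config$channel,
                               relativistic = config$relativistic,
                               energy_kev = as_beam(beam)$energy_kev,
                               inner_mrad = detector$inner_mrad,
                               outer_mrad = detector$outer_mrad,
                               backscattered = backsc, capped = capped))
}

#' Center/rim DF intensity versus nanoparticle diameter
#'
#' Simulates a centered gold sphere on the template scene for each diameter
#' and reports the mean detected fraction in a small disc at the sphere
#' center and in a rim annulus just inside the sphere edge. High-angle
#' scattering escape makes the center/rim ratio fall as the diameter grows.
#'
#' @param diameters Ascending sphere diameters, nm.
#' @param beam,detector,config Simulation settings.
#' @param dna_thickness DNA slab thickness under the sphere rim, nm.
#' @return Tibble `(diameter, center, rim, center_rim_ratio)` where
#'   `center`/`rim` are detected fractions.
#' @export
aunp_diameter_sweep <- function(diameters, beam = 30,
                                detector = annular_detector(15, 55),
                                config = mc_config(),
                                dna_thickness = 7.4) {
  if (any(diameters <= 0) || is.unsorted(diameters)) {
    abort("`diameters` must be positive and ascending.")
  }
  rows <- lapply(seq_along(diameters), function(di) {
    d <- diameters[di]
    r <- d / 2
    half <- max(20, d)
    scene <- specimen_scene(
      list(prim_slab(c(0, 0), 4 * half, 4 * half, 0, 3, 3 + dna_thickness, "dna"),
           prim_sphere(c(0, 0, 3 + dna_thickness + r), d, "gold")),
      bounds = c(-2, 2, -2, 2) * half)
    tables <- scene_tables(scene, beam, detector, config)
    sigma_max <- max(vapply(tables, function(t) 1 / t$lambda_total, numeric(1)))
    frac_at <- function(xs, ys, stream) {
      npx <- config$electrons_per_pixel
      det <- 0L; tot <- 0L
      for (i in seq_along(xs)) {
        set.seed(derive_seed(config$rng_seed, stream * 1000L + i))
        res <- trace_batch(scene, rep(xs[i], npx), rep(ys[i], npx),
                           tables, sigma_max, config)
        ok <- !is.na(res$exit_polar_mrad) &
          res$exit_polar_mrad >= detector$inner_mrad &
          res$exit_polar_mrad <= detector$outer_mrad
        det <- det + sum(ok); tot <- tot + npx
      }
      det / tot
    }
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    center <- frac_at(0, 0, di * 10L)
    rim <- frac_at(0.8 * r * cos(ang), 0.8 * r * sin(ang), di * 10L + 1L)
    tibble(diameter = d, center = center, rim = rim,
           center_rim_ratio = center / rim)
  })
  bind_rows(rows)
}

#' Secondary-electron proxy image
#'
#' The SE channel is modeled as surface-sensitive only: each pixel's expected
#' value is proportional to the SE yield of the topmost material under the
#' beam, with Poisson shot noise. Default yields make DNA indistinguishable
#' from the carbon film while gold is far brighter.
#'
#' @param scene An [specimen_scene()].
#' @param raster An [image_raster()].
#' @param yields Named per-material SE yields (>= 0); `vacuum` entry used
#'   where the window is bare.
#' @param dose Expected counts per pixel at yield 1.
#' @param rng_seed Seed.
#' @return An [stem_image()] with channel `"SE"`.
#' @export
se_proxy_image <- function(scene, raster = image_raster(64, 48, 1),
                           yields = c(dna = 0.05, carbon = 0.05, gold = 1,
                                      vacuum = 0),
                           dose = 200, rng_seed = 1) {
  if (any(yields < 0)) abort("SE yields must be >= 0.")
  co <- raster_coords(raster)
  idx <- topmost_index_at(scene, as.numeric(co$x), as.numeric(co$y))
  nms <- c(scene$support$name, map_chr_(scene$primitives, function(p) p$material$name))
  mat <- nms[pmax(idx, 0L) + 1L]
  mat[idx < 0L] <- "vacuum"
  y <- yields[mat]
  y[is.na(y)] <- 0
  set.seed(derive_seed(rng_seed, 0L))
  counts <- matrix(rpois(length(y), dose * y), raster$ny, raster$nx)
  stem_image(counts, pixel_size = raster$pixel_size, channel = "SE",
             provenance = list(kind = "se_proxy", seed = rng_seed,
                               dose = dose, yields = yields))
}
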