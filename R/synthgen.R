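# Seeded generator of labeled synthetic data at three scales: posture
# geometries, 128x128 mask crops for network training, and full well
# snapshots. All sampling uses R's global RNG; entry points take a seed.

# operational posture boundaries (radians / multiples of mean body width)
POSTURE_RULES <- list(
  near_min = pi,            # NearCurled: pi <= T < 5*pi/3
  curled_min = 5 * pi / 3,  # Curled:     T >= 5*pi/3 with head-tail contact
  contact_widths = 1.5      # contact: head-tail distance < 1.5 mean widths
)

#' Classify a geometry by the operational posture rules
#'
#' Coiled: the rendered mask encloses a hole (self-occluding loop).
#' Curled: total turning at least 5pi/3 with the head-tail distance under
#' 1.5 mean body widths. NearCurled: total turning in `[pi, 5pi/3)`.
#' NonCurled: total turning under pi. Returns `NA` for geometries that
#' satisfy no rule (e.g. high turning without head-tail contact).
#'
#' @param geometry A [worm_geometry()].
#' @param mask Optional pre-rendered binary mask (rendered on demand).
#' @return One of [posture_classes()] (never `"Censored"`), or `NA`.
#' @export
posture_rule_class <- function(geometry, mask = NULL) {
  if (is.null(mask)) {
    ext <- ceiling(geometry$body_length + 4 * max(geometry$r) + 8)
    mask <- render_mask(geometry, c(ext, ext))
  }
  if (cpp_count_holes(mask) >= 1) return("Coiled")
  m <- morphology(geometry)
  tt <- m$total_turning
  if (tt >= POSTURE_RULES$curled_min) {
    contact <- m$head_tail_distance <
      POSTURE_RULES$contact_widths * 2 * m$mean_half_width
    return(if (contact) "Curled" else NA_character_)
  }
  if (tt >= POSTURE_RULES$near_min) return("NearCurled")
  "NonCurled"
}

# fit alpha coefficients so that the spline reproduces a target angle curve
theta_to_alpha <- function(u, th, basis = spline_basis()) {
  qr.solve(basis_matrix(basis, u), th)
}

#' Sample a random worm geometry of a given posture class
#'
#' Body length, width profile, orientation and undulation are drawn from
#' ranges typical of adult animals at the assay's image scale; candidates
#' are re-drawn until the geometry passes its own class rule
#' ([posture_rule_class()]), so labels are correct by construction.
#'
#' @param class One of the four worm classes (`"Censored"` is assembled by
#'   the snapshot/crop generators, not sampled as a geometry).
#' @param basis A [spline_basis()].
#' @return A [worm_geometry()].
#' @export
sample_posture <- function(class = posture_classes(worm_only = TRUE),
                           basis = spline_basis()) {
  class <- match.arg(class)
  u <- seq(0, 1, length.out = 161)
  for (attempt in seq_len(200)) {
    L <- runif(1, 50, 70)
    w <- runif(1, 2.2, 3.0)
    rprof <- w * c(0.12, 0.55, 0.9, 1, 1, 0.9, 0.55, 0.12) *
      runif(8, 0.92, 1.08)
    theta0 <- runif(1, 0, 2 * pi)
    sgn <- sample(c(-1, 1), 1)
    ph <- runif(1, 0, 2 * pi)
    th <- switch(class,
      NonCurled = {
        k <- runif(1, 0.8, 1.6)
        f <- sin(2 * pi * k * u + ph)
        tt <- runif(1, 0.25, 0.85) * pi
        scale <- tt / sum(abs(diff(f)))    # exact: turning linear in amplitude
        theta0 + sgn * scale * f
      },
      NearCurled = theta0 + sgn * (runif(1, 1.06, 1.58) * pi * u +
                                     runif(1, 0, 0.15) * sin(2 * pi * u + ph)),
      Curled = theta0 + sgn * (runif(1, 1.86, 1.96) * pi * u +
                                 runif(1, 0, 0.06) * sin(2 * pi * u + ph)),
      Coiled = theta0 + sgn * (runif(1, 2.1, 2.6) * pi * u +
                                 runif(1, 0, 0.10) * sin(2 * pi * u + ph)))
    geom <- try(worm_geometry(theta_to_alpha(u, th, basis), rprof, L,
                              basis = basis), silent = TRUE)
    if (inherits(geom, "try-error")) next
    cls <- tryCatch(posture_rule_class(geom), error = function(e) NA)
    if (identical(cls, class)) return(geom)
  }
  stop("failed to sample a ", class, " geometry after 200 attempts")
}

# integer shift with zero padding (dim1 = x)
shift_mat <- function(m, dx, dy) {
  W <- nrow(m); H <- ncol(m)
  out <- matrix(0, W, H)
  xs <- seq_len(W) - dx; ys <- seq_len(H) - dy
  okx <- xs >= 1 & xs <= W; oky <- ys >= 1 & ys <= H
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# assemble a training crop the way the segmenter produces them: shaded
# foreground on the well background, sensor noise, then grayscale retained
# under the object's dilated mask (so crops carry the same background ring
# the deployed pipeline sees), plus a small random translation
assemble_crop <- function(fg, size = 128, noise_sd = 0.02,
                          intensity = runif(1, 0.8, 1)) {
  mask <- fg > 0
  img <- matrix(0.07, size, size)
  img[mask] <- (0.55 + 0.45 * fg[mask]) * intensity
  img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
  img[img < 0] <- 0; img[img > 1] <- 1
  crop <- standardize_crop(img, mask, size = size)
  shift_mat(crop, sample(-10:10, 1), sample(-10:10, 1))
}

# single worm crop
worm_crop <- function(geom, size = 128) {
  assemble_crop(render_worm_gray(geom, c(size, size)), size)
}

largest_component <- function(mask) {
  lab <- cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  n <- attr(lab, "n")
  if (n <= 1) return(mask != 0)
  keep <- which.max(tabulate(lab[lab > 0], n))
  lab == keep
}

n_components <- function(mask) {
  attr(cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask))), "n")
}

# censored crop content: entangled pairs, debris specks, fragments,
# ragged/noisy bodies -- always exactly one 8-connected object. The
# foreground (shaded elevation field) is built first, then assembled onto
# the well background like any segmented crop.
censored_crop <- function(type = c("pair", "speck", "fragment", "noisy"),
                          size = 128) {
  type <- match.arg(type)
  for (attempt in seq_len(100)) {
    noise_sd <- 0.02
    fg <- switch(type,
      pair = {
        f1 <- render_worm_gray(sample_posture(sample(WORM_CLASSES, 1)),
                               c(size, size))
        f2 <- render_worm_gray(sample_posture(sample(WORM_CLASSES, 1)),
                               c(size, size))
        f2 <- shift_mat(f2, sample(-14:14, 1), sample(-14:14, 1))
        u <- pmax(f1, f2 * runif(1, 0.8, 1))
        # an untangled pair would be a mislabeled single worm: require the
        # two bodies to actually touch
        if (n_components(u > 0) != 1) NULL else u
      },
      speck = {
        out <- matrix(0, size, size)
        nb <- sample(2:4, 1)
        cx <- size / 2 + runif(1, -8, 8); cy <- size / 2 + runif(1, -8, 8)
        for (i in seq_len(nb)) {
          out <- pmax(out, cpp_render_tube_gray(cx + runif(1, -3, 3),
                                                cy + runif(1, -3, 3),
                                                runif(1, 2.5, 4.5),
                                                size, size))
        }
        out
      },
      fragment = {
        g <- sample_posture(sample(WORM_CLASSES, 1))
        full <- render_worm_gray(g, c(size, size))
        ang <- runif(1, 0, 2 * pi)
        cut <- runif(1, -6, 6)
        xg <- row(full) - size / 2; yg <- col(full) - size / 2
        full[cos(ang) * xg + sin(ang) * yg > cut] <- 0
        full
      },
      noisy = {
        noise_sd <- 0.06
        full <- render_worm_gray(sample_posture(sample(WORM_CLASSES, 1)),
                                 c(size, size))
        mask <- full > 0
        band <- mask & !EBImage::erode(mask + 0, EBImage::makeBrush(5, "box"))
        full[band & matrix(runif(size^2) < 0.5, size, size)] <- 0
        # heavy multiplicative speckle on the remaining body
        full * matrix(pmax(1 + rnorm(size^2, 0, 0.35), 0.2), size, size)
      })
    if (is.null(fg)) next
    m <- largest_component(fg)
    fg[!m] <- 0
    if (sum(m) < 12) next
    crop <- assemble_crop(fg, size, noise_sd = noise_sd)
    if (n_components(crop > 0) == 1) return(crop)
  }
  stop("failed to build a censored crop of type ", type)
}

to_raw_images <- function(imgs, size = 128) {
  arr <- as.raw(pmin(pmax(round(unlist(imgs) * 255), 0), 255))
  dim(arr) <- c(size, size, length(imgs))
  arr
}

#' Generate a balanced labeled mask-crop dataset
#'
#' Produces `n_per_class` crops for each of the four worm posture classes
#' plus a Censored pool (default equal in size to the whole worm pool)
#' assembled from entangled worm pairs (40\%), progeny-sized debris specks
#' (20\%), body fragments (20\%) and ragged high-noise bodies (20\%).
#' Every crop contains exactly one 8-connected object.
#'
#' @param n_per_class Crops per worm class (>= 1).
#' @param seed Optional RNG seed.
#' @param n_censored Size of the Censored pool (default `4 * n_per_class`).
#' @param size Crop side length in pixels.
#' @return A `mask_dataset`: list with `images` (raw array
#'   `size x size x N`, intensities 0-255), `labels` (factor over
#'   [posture_classes()]), and `meta` (per-crop provenance).
#' @export
generate_mask_dataset <- function(n_per_class, seed = NULL,
                                  n_censored = 4 * n_per_class, size = 128) {
  stopifnot(n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  imgs <- vector("list", 4 * n_per_class + n_censored)
  labels <- character(length(imgs))
  source_type <- character(length(imgs))
  i <- 0
  for (cls in WORM_CLASSES) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      imgs[[i]] <- worm_crop(sample_posture(cls), size)
      labels[i] <- cls
      source_type[i] <- "worm"
    }
  }
  cens_types <- rep(c("pair", "pair", "speck", "fragment", "noisy"),
                    length.out = n_censored)
  for (k in seq_len(n_censored)) {
    i <- i + 1
    imgs[[i]] <- censored_crop(cens_types[k], size)
    labels[i] <- "Censored"
    source_type[i] <- cens_types[k]
  }
  structure(list(images = to_raw_images(imgs, size),
                 labels = factor(labels, levels = POSTURE_CLASSES),
                 meta = data.frame(index = seq_along(labels),
                                   label = labels, source = source_type)),
            class = "mask_dataset")
}

#' @export
print.mask_dataset <- function(x, ...) {
  cat("mask_dataset:", length(x$labels), "crops\n")
  print(table(x$labels))
  invisible(x)
}

#' Subset a mask dataset
#'
#' @param dataset A `mask_dataset`.
#' @param idx Integer indices.
#' @return A `mask_dataset` with the selected crops.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(images = dataset$images[, , idx, drop = FALSE],
                 labels = dataset$labels[idx],
                 meta = dataset$meta[idx, , drop = FALSE]),
            class = "mask_dataset")
}

#' Well specification for the snapshot generator
#'
#' Encodes the per-well assay structure: expected worm count, the
#' per-worm probability of a curled-family posture at snapshot time, and
#' nuisance levels (noise, debris, overlap). `curl_probability` splits
#' among Coiled/Curled/NearCurled by `family_split`.
#'
#' @param condition_id Condition label.
#' @param curl_probability Per-worm chance of a curled-family posture.
#' @param n_worms Worm count (used as Poisson mean by [generate_screen()]).
#' @param well_radius Well radius in pixels.
#' @param noise_level Gaussian background noise sd (8-bit scale 0-1).
#' @param debris_rate Poisson mean of debris items per well.
#' @param seed Optional per-well seed.
#' @param overlap_fraction Probability a worm is placed touching another.
#' @param image_size Canvas side in pixels.
#' @param family_split Probabilities of Coiled/Curled/NearCurled within
#'   the curled family.
#' @param role Plate-map role: `"drug"`, `"vehicle"` or `"control"`.
#' @param decay Per-minute linear drift of `curl_probability` (time decay
#'   of the curling signal after transfer to liquid).
#' @return A `well_spec` list.
#' @export
well_spec <- function(condition_id, curl_probability = 0.2, n_worms = 12,
                      well_radius = 170, noise_level = 0.02, debris_rate = 1,
                      seed = NULL, overlap_fraction = 0.05, image_size = 384,
                      family_split = c(0.5, 0.25, 0.25), role = "drug",
                      decay = 0) {
  stopifnot(curl_probability >= 0, curl_probability <= 1, n_worms >= 0,
            well_radius > 0, noise_level >= 0, debris_rate >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1)
  structure(list(condition_id = condition_id,
                 curl_probability = curl_probability, n_worms = n_worms,
                 well_radius = well_radius, noise_level = noise_level,
                 debris_rate = debris_rate, seed = seed,
                 overlap_fraction = overlap_fraction, image_size = image_size,
                 family_split = family_split / sum(family_split),
                 role = role, decay = decay),
            class = "well_spec")
}

draw_posture_class <- function(spec, n, curl_probability = NULL) {
  p <- if (is.null(curl_probability)) spec$curl_probability else curl_probability
  curled <- runif(n) < p
  cls <- rep("NonCurled", n)
  if (any(curled))
    cls[curled] <- sample(c("Coiled", "Curled", "NearCurled"), sum(curled),
                          replace = TRUE, prob = spec$family_split)
  cls
}

# jagged star-shaped debris blob (polar inside test over its bbox)
render_star <- function(canvas, cx, cy, base, amp, k, intensity = 0.8) {
  W <- nrow(canvas); H <- ncol(canvas)
  rad <- ceiling(base * (1 + amp)) + 1
  xs <- max(1, floor(cx - rad)):min(W, ceiling(cx + rad))
  ys <- max(1, floor(cy - rad)):min(H, ceiling(cy + rad))
  for (y in ys) for (x in xs) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    if (d <= base * (1 + amp * cos(k * atan2(dy, dx))))
      canvas[x, y] <- max(canvas[x, y], intensity)
  }
  canvas
}

#' Generate one synthetic well snapshot with ground truth
#'
#' Bright worms on a dark background inside a circular well with a
#' vignetted meniscus ring, Gaussian sensor noise, and optional debris
#' (sub-worm specks and jagged blobs). Worms are placed with a hard-core
#' minimum centroid spacing except for a controllable fraction placed
#' overlapping a neighbor (ground truth flags both as overlapped).
#'
#' @param spec A [well_spec()].
#' @param classes Optional preassigned posture classes (length `n_worms`);
#'   drawn from `curl_probability` when omitted.
#' @return List with `image` (matrix `image_size x image_size`, 0-1),
#'   `truth` (per-worm data.frame), `well` (center/radius), `spec`.
#' @export
generate_snapshot <- function(spec, classes = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  W <- spec$image_size
  ctr <- (W + 1) / 2
  R <- spec$well_radius
  if (is.null(classes)) classes <- draw_posture_class(spec, spec$n_worms)
  stopifnot(length(classes) == spec$n_worms)

  # background: dark field, well disk slightly lighter, meniscus ring
  xg <- matrix(seq_len(W), W, W); yg <- t(xg)
  d <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  img <- matrix(0.03, W, W)
  img[d <= R] <- 0.07
  img <- img + 0.10 * exp(-((d - 0.97 * R) / (0.035 * R))^2) * (d <= R + 2)

  truth <- NULL
  placed <- NULL   # centroids
  # occupancy with inflated radii guarantees pixel-level separation of
  # non-overlapping worms (centroid spacing alone lets long bodies touch)
  occupied <- matrix(0L, W, W)
  clearance <- 4
  for (i in seq_len(spec$n_worms)) {
    geom <- sample_posture(classes[i])
    smp <- tube_samples(geom)
    mx <- mean(smp$x); my <- mean(smp$y)
    overlap <- (i > 1) && runif(1) < spec$overlap_fraction
    pos <- NULL; cand_mask <- NULL
    for (attempt in seq_len(150)) {
      if (overlap) {
        j <- sample(seq_len(i - 1), 1)
        ang <- runif(1, 0, 2 * pi)
        cand <- placed[j, ] + runif(1, 6, 14) * c(cos(ang), sin(ang))
      } else {
        ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (R - 48)
        cand <- c(ctr + rr * cos(ang), ctr + rr * sin(ang))
      }
      if (sqrt(sum((cand - c(ctr, ctr))^2)) > R - 44) next
      cx <- smp$x - mx + cand[1]
      cy <- cand[2] - (smp$y - my)   # y-flip of centered samples
      m <- cpp_render_tube(cx, cy, smp$r + clearance, W, W)
      if (!overlap && any(occupied[m == 1] == 1)) next
      pos <- cand; cand_mask <- m
      break
    }
    if (is.null(pos))
      stop("cannot place ", spec$n_worms,
           " worms in the well; reduce n_worms or enlarge well_radius")
    occupied[cand_mask == 1] <- 1L
    cx <- smp$x - mx + pos[1]
    cy <- pos[2] - (smp$y - my)
    gw <- cpp_render_tube_gray(cx, cy, smp$r, W, W) *
      runif(1, 0.8, 1)
    img <- pmax(img, (0.55 + 0.45 * gw) * (gw > 0))
    placed <- rbind(placed, pos)
    truth <- rbind(truth, data.frame(
      worm_id = i, class = classes[i], x = pos[1], y = pos[2],
      overlapped = overlap, body_length = geom$body_length))
    if (overlap) truth$overlapped[truth$worm_id == j] <- TRUE
  }

  # debris
  n_debris <- rpois(1, spec$debris_rate)
  debris <- NULL
  for (k in seq_len(n_debris)) {
    ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (R - 30)
    cx <- ctr + rr * cos(ang); cy <- ctr + rr * sin(ang)
    if (runif(1) < 0.5) {  # tiny speck, below the area filter
      img <- pmax(img, cpp_render_tube_gray(cx, cy, runif(1, 0.8, 1.6), W, W) * 0.8)
      debris <- rbind(debris, data.frame(x = cx, y = cy, type = "speck"))
    } else {               # worm-scale jagged blob, caught by jaggedness
      img <- render_star(img, cx, cy, runif(1, 7, 10), runif(1, 0.65, 0.85),
                         sample(9:14, 1))
      debris <- rbind(debris, data.frame(x = cx, y = cy, type = "jagged"))
    }
  }

  img <- img + matrix(rnorm(W * W, 0, spec$noise_level), W, W)
  img[img < 0] <- 0; img[img > 1] <- 1
  if (is.null(truth))
    truth <- data.frame(worm_id = integer(), class = character(),
                        x = numeric(), y = numeric(),
                        overlapped = logical(), body_length = numeric())
  list(image = img, truth = truth, debris = debris,
       well = list(center = c(ctr, ctr), radius = R), spec = spec)
}

#' Generate a multi-condition snapshot screen
#'
#' For each condition and well, draws a worm count from a Poisson with the
#' template's `n_worms` as mean, then resamples every worm's posture
#' independently for each snapshot (stills taken 30 s - 2 min apart are
#' effectively independent draws of the posture distribution). A
#' condition's `decay` field drifts its `curl_probability` linearly with
#' the round start time, emulating the post-transfer decay of the curling
#' signal. With `render = TRUE`, well images are written as PNG to
#' `out_dir` together with `plate_map.csv` and `truth.csv`.
#'
#' @param conditions List of [well_spec()] templates (unique
#'   `condition_id`s).
#' @param wells_per_condition Wells per condition.
#' @param rounds Snapshot rounds.
#' @param snapshots_per_round Snapshots per round per well.
#' @param seed RNG seed.
#' @param render Render and write images (else truth tables only).
#' @param out_dir Output directory when rendering.
#' @param round_times Round start times in minutes after transfer.
#' @return List with `truth`, `plate_map`, and (when rendering)
#'   `manifest` of written image files.
#' @export
generate_screen <- function(conditions, wells_per_condition, rounds = 3,
                            snapshots_per_round = 7, seed = NULL,
                            render = FALSE, out_dir = NULL,
                            round_times = seq(0, by = 20,
                                              length.out = rounds)) {
  stopifnot(length(conditions) >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (render && is.null(out_dir)) stop("render = TRUE requires out_dir")
  if (render) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # truth rows accumulate as plain vectors (a screen can hold hundreds of
  # thousands of worm-still observations)
  acc <- list(worm_id = list(), class = list(), x = list(), y = list(),
              overlapped = list(), body_length = list(), condition = list(),
              well = list(), round = list(), snapshot = list(),
              time_min = list())
  manifest <- list(); plate <- list()
  ti <- 0
  push <- function(worm_id, cls, x, y, ov, bl, cond, well_id, rd, sn, t_min) {
    ti <<- ti + 1
    n <- length(worm_id)
    acc$worm_id[[ti]] <<- worm_id
    acc$class[[ti]] <<- cls
    acc$x[[ti]] <<- x; acc$y[[ti]] <<- y
    acc$overlapped[[ti]] <<- ov
    acc$body_length[[ti]] <<- bl
    acc$condition[[ti]] <<- rep(cond, n)
    acc$well[[ti]] <<- rep(well_id, n)
    acc$round[[ti]] <<- rep(rd, n)
    acc$snapshot[[ti]] <<- rep(sn, n)
    acc$time_min[[ti]] <<- rep(t_min, n)
  }
  for (spec in conditions) {
    for (wl in seq_len(wells_per_condition)) {
      well_id <- sprintf("%s_W%02d", spec$condition_id, wl)
      plate[[well_id]] <- data.frame(well = well_id,
                                     condition = spec$condition_id,
                                     role = spec$role)
      n_w <- rpois(1, spec$n_worms)
      for (rd in seq_len(rounds)) {
        t_min <- round_times[rd]
        p_eff <- min(max(spec$curl_probability + spec$decay * t_min, 0), 1)
        for (sn in seq_len(snapshots_per_round)) {
          cls <- draw_posture_class(spec, n_w, p_eff)
          if (render) {
            snap_spec <- spec; snap_spec$n_worms <- n_w; snap_spec$seed <- NULL
            snap <- generate_snapshot(snap_spec, classes = cls)
            file <- file.path(out_dir, sprintf("%s_R%d_S%d.png",
                                               well_id, rd, sn))
            write_snapshot(snap$image, file)
            tr <- snap$truth
            manifest[[length(manifest) + 1]] <- data.frame(
              file = file, condition = spec$condition_id, well = well_id,
              round = rd, snapshot = sn, time_min = t_min)
            if (nrow(tr) > 0)
              push(tr$worm_id, tr$class, tr$x, tr$y, tr$overlapped,
                   tr$body_length, spec$condition_id, well_id, rd, sn, t_min)
          } else if (n_w > 0) {
            push(seq_len(n_w), cls, rep(NA_real_, n_w), rep(NA_real_, n_w),
                 rep(FALSE, n_w), rep(NA_real_, n_w),
                 spec$condition_id, well_id, rd, sn, t_min)
          }
        }
      }
    }
  }
  if (ti == 0)
    acc <- list(worm_id = integer(), class = character(), x = numeric(),
                y = numeric(), overlapped = logical(),
                body_length = numeric(), condition = character(),
                well = character(), round = integer(), snapshot = integer(),
                time_min = numeric())
  truth <- data.frame(
    worm_id = unlist(acc$worm_id), class = unlist(acc$class),
    x = unlist(acc$x), y = unlist(acc$y),
    overlapped = unlist(acc$overlapped),
    body_length = unlist(acc$body_length),
    condition = unlist(acc$condition), well = unlist(acc$well),
    round = unlist(acc$round), snapshot = unlist(acc$snapshot),
    time_min = unlist(acc$time_min))
  plate_map <- do.call(rbind, plate)
  rownames(plate_map) <- NULL
  manifest <- if (length(manifest)) do.call(rbind, manifest) else NULL
  if (render) {
    write.csv(plate_map, file.path(out_dir, "plate_map.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(truth = truth, plate_map = plate_map, manifest = manifest)
}
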