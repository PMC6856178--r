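# Synthetic sperm-video simulator: bright sperm-like particles on a noisy
# dark background. Three kinematic classes define the ground-truth motility
# triple exactly: directed movers (progressive), confined jitterers
# (non-progressive) and static particles (immotile).

# Largest-remainder apportionment of n into counts proportional to fractions.
# Deterministic: ties broken by class order.
largestRemainderCounts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Simulate particle tracks for a synthetic semen-sample video
#'
#' Assigns particles to the three motility classes by largest-remainder
#' rounding of \code{classFractions(spec) * nParticles}, then integrates
#' per-frame motion: progressive particles advance along a persistent
#' heading perturbed by Gaussian heading noise; non-progressive particles
#' random-walk inside a confinement disc around their anchor; immotile
#' particles tremble sub-pixel around their start. Positions are reflected
#' at the frame borders so the particle count is constant.
#'
#' @param spec a \code{\link{syntheticVideoSpec}}.
#' @param kin a \code{\link{kinematicsParams}}.
#' @return A list with \code{positions} (array nParticles x 2 x nFrames of
#'   (row, col) px coordinates), \code{class} (factor: progressive /
#'   nonprogressive / immotile), \code{heading} (per-particle final heading,
#'   radians) and \code{counts} (per-class particle counts).
#' @examples
#' tr <- simulateTracks(syntheticVideoSpec(nParticles = 10, nFrames = 20),
#'                      kinematicsParams())
#' table(tr$class)
#' @export
simulateTracks <- function(spec, kin = kinematicsParams()) {
  stopifnot(is(spec, "SyntheticVideoSpec"), is(kin, "KinematicsParams"))
  validObject(spec); validObject(kin)
  n <- as.integer(spec@nParticles)
  if (n == 0) stop("empty scene: nParticles must be >= 1")
  counts <- largestRemainderCounts(spec@classFractions, n)
  cls <- factor(rep(c("progressive", "nonprogressive", "immotile"), counts),
                levels = c("progressive", "nonprogressive", "immotile"))
  h <- spec@frameSize[1]; w <- spec@frameSize[2]
  tFrames <- as.integer(spec@nFrames)
  set.seed(as.integer(spec@seed))
  margin <- min(spec@headRadius + 1, min(h, w) / 4)
  pos <- array(0, c(n, 2, tFrames))
  start <- cbind(runif(n, margin, h - margin), runif(n, margin, w - margin))
  heading <- runif(n, 0, 2 * pi)
  cur <- start
  anchor <- start
  for (t in seq_len(tFrames)) {
    if (t > 1) {
      step <- matrix(0, n, 2)
      ip <- cls == "progressive"
      if (any(ip)) {
        heading[ip] <- heading[ip] +
          rnorm(sum(ip), 0, kin@progressiveHeadingSigma)
        step[ip, 1] <- kin@progressiveSpeed * sin(heading[ip])
        step[ip, 2] <- kin@progressiveSpeed * cos(heading[ip])
      }
      inp <- cls == "nonprogressive"
      if (any(inp))
        step[inp, ] <- matrix(rnorm(2 * sum(inp), 0, kin@nonprogJitter),
                              ncol = 2)
      cur <- cur + step
      # confine non-progressive particles to a disc around their anchor
      if (any(inp)) {
        d <- cur[inp, , drop = FALSE] - anchor[inp, , drop = FALSE]
        r <- sqrt(rowSums(d^2))
        over <- r > kin@nonprogConfineRadius
        if (any(over)) {
          scale <- kin@nonprogConfineRadius / r
          idx <- which(inp)[over]
          cur[idx, ] <- anchor[idx, , drop = FALSE] +
            d[over, , drop = FALSE] * scale[over]
        }
      }
      # immotile: fresh sub-pixel offset from the start point each frame
      im <- cls == "immotile"
      if (any(im) && kin@immotileJitter > 0) {
        ang <- runif(sum(im), 0, 2 * pi)
        rad <- sqrt(runif(sum(im))) * kin@immotileJitter / 2
        cur[im, ] <- start[im, , drop = FALSE] + cbind(rad * sin(ang),
                                                       rad * cos(ang))
      }
      # reflect at borders (and flip the heading component that hit)
      for (ax in 1:2) {
        lim <- c(h, w)[ax]
        lo <- cur[, ax] < 1
        cur[lo, ax] <- 2 - cur[lo, ax]
        hi <- cur[, ax] > lim
        cur[hi, ax] <- 2 * lim - cur[hi, ax]
        if (any(lo | hi)) {
          flip <- (lo | hi) & ip
          if (ax == 1) heading[flip] <- -heading[flip]
          else heading[flip] <- pi - heading[flip]
        }
        cur[, ax] <- clipRange(cur[, ax], 1, lim)
      }
    }
    pos[, , t] <- cur
  }
  list(positions = pos, class = cls, heading = heading,
       counts = setNames(counts, levels(cls)))
}

# Render one frame: noisy dark background plus a smooth bright disc per
# particle, with a short 1-px tail opposite the heading for progressive
# particles. Intensities clipped to [0, 255].
renderOneFrame <- function(coords, cls, heading, spec, background) {
  h <- spec@frameSize[1]; w <- spec@frameSize[2]
  img <- background
  r <- spec@headRadius
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(coords))) {
    cy <- coords[i, 1]; cx <- coords[i, 2]
    y0 <- max(1, floor(cy - r - 2)); y1 <- min(h, ceiling(cy + r + 2))
    x0 <- max(1, floor(cx - r - 2)); x1 <- min(w, ceiling(cx + r + 2))
    if (y0 > y1 || x0 > x1) next
    dy <- rows[y0:y1, x0:x1] - cy
    dx <- cols[y0:y1, x0:x1] - cx
    d2 <- dy^2 + dx^2
    # flat-topped smooth disc: near-constant inside radius r, soft edge
    blob <- 235 * exp(-(d2 / r^2)^2)
    img[y0:y1, x0:x1] <- pmax(img[y0:y1, x0:x1], background[y0:y1, x0:x1] + blob)
    if (!is.null(cls) && cls[i] == "progressive") {
      # short tail opposite the heading
      for (s in seq(r, r + 3, by = 0.5)) {
        ty <- round(cy - s * sin(heading[i])); tx <- round(cx - s * cos(heading[i]))
        if (ty >= 1 && ty <= h && tx >= 1 && tx <= w)
          img[ty, tx] <- max(img[ty, tx], background[ty, tx] + 120)
      }
    }
  }
  clipRange(img, 0, 255)
}

#' Render simulated tracks into video frames
#'
#' Each frame is a dark background with additive Gaussian noise
#' (sd \code{noiseSigma}) on which every particle is drawn as a bright
#' smooth-edged disc of radius \code{headRadius}; progressive particles get
#' a short 1-px tail opposite their heading. Pixels live on the 8-bit scale.
#'
#' @param tracks result of \code{\link{simulateTracks}}.
#' @param spec the \code{\link{syntheticVideoSpec}} used for the tracks.
#' @param sourceId identifier stored on the returned sequence.
#' @return A \code{\link{frameSequence}} of greyscale frames.
#' @export
renderFrames <- function(tracks, spec, sourceId = "synthetic") {
  stopifnot(is(spec, "SyntheticVideoSpec"))
  h <- spec@frameSize[1]; w <- spec@frameSize[2]
  if (min(h, w) < 2 * spec@headRadius)
    stop("frameSize must be at least twice the head radius in both dimensions")
  tFrames <- dim(tracks$positions)[3]
  if (tFrames != spec@nFrames)
    stop("track length does not match spec nFrames")
  set.seed(as.integer(spec@seed) + 1000003L)  # independent noise stream
  bgLevel <- 20
  fr <- vector("list", tFrames)
  for (t in seq_len(tFrames)) {
    bg <- matrix(bgLevel, h, w)
    if (spec@noiseSigma > 0)
      bg <- bg + matrix(rnorm(h * w, 0, spec@noiseSigma), h, w)
    bg <- clipRange(bg, 0, 255)
    fr[[t]] <- renderOneFrame(matrix(tracks$positions[, , t], ncol = 2),
                              tracks$class, tracks$heading, spec, bg)
  }
  frameSequence(fr, fps = spec@fps, sourceId = sourceId)
}

#' Generate a synthetic participant cohort
#'
#' Simulates \code{nVideos} semen-sample videos with per-video motility-class
#' fractions drawn from a Dirichlet distribution, renders them, and draws
#' VISEM-style participant covariates (age, BMI, abstinence days, sperm
#' concentration). The motility label of video i is exactly its class
#' fractions times 100 — ground truth is exact by construction. An optional
#' linear association knob couples BMI to the progressive percentage
#' (slope 0 = independent covariates).
#'
#' @param nVideos number of videos/participants.
#' @param specTemplate \code{\link{syntheticVideoSpec}} whose fields other
#'   than \code{classFractions} and \code{seed} are used for every video.
#' @param kin \code{\link{kinematicsParams}}.
#' @param seed master seed; all per-video seeds and covariates derive from it.
#' @param dirichletAlpha concentration parameters of the label sampler.
#' @param bmiSlope change in BMI per percentage point of progressive
#'   motility (0 = independent).
#' @param renderVideos if \code{FALSE}, only tracks/labels/covariates are
#'   produced (fast path for feature-free tests).
#' @return A list with \code{videos} (list of FrameSequence or NULL),
#'   \code{tracks} (list), \code{labels} (data.frame id/progressive/
#'   non_progressive/immotile), \code{participants} (data.frame id/age/bmi/
#'   abstinence_days/concentration) and \code{table} (the combined
#'   VISEM-style data.frame).
#' @export
generateCohort <- function(nVideos, specTemplate = syntheticVideoSpec(),
                           kin = kinematicsParams(), seed = 1,
                           dirichletAlpha = c(2, 1.5, 2), bmiSlope = 0,
                           renderVideos = TRUE) {
  if (nVideos < 1) stop("nVideos must be >= 1")
  if (any(dirichletAlpha <= 0)) stop("dirichletAlpha must be positive")
  set.seed(as.integer(seed))
  # Dirichlet draws via normalised gammas
  g <- matrix(stats::rgamma(nVideos * 3, shape = rep(dirichletAlpha,
                                                     each = nVideos)),
              nVideos, 3)
  fractions <- g / rowSums(g)
  age <- round(runif(nVideos, 18, 55), 1)
  abst <- round(runif(nVideos, 0, 10), 1)
  conc <- round(exp(rnorm(nVideos, log(60), 0.6)), 1)
  bmiNoise <- rnorm(nVideos, 0, 3)
  ids <- sprintf("video_%03d", seq_len(nVideos))
  videos <- vector("list", nVideos); tracksList <- vector("list", nVideos)
  labels <- matrix(0, nVideos, 3)
  for (i in seq_len(nVideos)) {
    sp <- specTemplate
    sp@classFractions <- fractions[i, ]
    sp@seed <- as.integer(seed) + 7919L * i
    tr <- simulateTracks(sp, kin)
    tracksList[[i]] <- tr
    # label from the realised (largest-remainder) particle counts so the
    # triple is exact for the rendered scene
    labels[i, ] <- 100 * tr$counts / sum(tr$counts)
    if (renderVideos) videos[[i]] <- renderFrames(tr, sp, sourceId = ids[i])
  }
  bmi <- round(24 + bmiSlope * (labels[, 1] - mean(labels[, 1])) + bmiNoise, 1)
  bmi <- pmax(bmi, 15)
  labDf <- data.frame(id = ids, progressive = labels[, 1],
                      non_progressive = labels[, 2], immotile = labels[, 3],
                      stringsAsFactors = FALSE)
  part <- data.frame(id = ids, age = age, bmi = bmi, abstinence_days = abst,
                     concentration = conc, stringsAsFactors = FALSE)
  tbl <- data.frame(id = ids, progressive = labels[, 1],
                    non_progressive = labels[, 2], immotile = labels[, 3],
                    concentration = conc, age = age, bmi = bmi,
                    abstinence_days = abst, stringsAsFactors = FALSE)
  list(videos = videos, tracks = tracksList, labels = labDf,
       participants = part, table = tbl)
}

#' Write a cohort to disk as PNG frame directories plus a CSV
#'
#' Lays out one directory of numbered PNG frames per video (the frame-
#' directory format \code{\link{readVideo}} consumes) and a VISEM-style CSV
#' with columns id, progressive, non_progressive, immotile, concentration,
#' age, bmi, abstinence_days.
#'
#' @param cohort result of \code{\link{generateCohort}} (rendered).
#' @param dir output directory, created if needed.
#' @return The CSV path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$videos)) {
    v <- cohort$videos[[i]]
    if (is.null(v)) stop("cohort was generated with renderVideos = FALSE")
    writeFrameDir(v, file.path(dir, cohort$labels$id[i]))
  }
  csv <- file.path(dir, "cohort.csv")
  writeLines(cohortCsvLines(cohort$table), csv)
  invisible(csv)
}

# Deterministic CSV serialisation (byte-identical across runs per seed).
cohortCsvLines <- function(tbl) {
  hdr <- paste(names(tbl), collapse = ",")
  rows <- apply(tbl, 1, function(r) paste(trimws(unname(r)), collapse = ","))
  c(hdr, rows)
}
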