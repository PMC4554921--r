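#' Describe a synthetic immunogold labelling experiment
#'
#' Fixes how synthetic micrograph scenes are generated: the true proportion
#' of gold particles over each compartment, particles and micrographs per
#' scene set, the localization jitter (antibody-gold displacement), the
#' primary-antibody dilution series, and the share of no-primary-antibody
#' control micrographs.
#'
#' @param compartmentFractions named numeric vector of proportions over
#'   \code{plasma_membrane}, \code{cisternae}, \code{flagellum}; must sum
#'   to 1.
#' @param nParticles gold particles per non-control micrograph (>= 1).
#' @param nMicrographs number of labelled micrographs (>= 1).
#' @param jitterSd isotropic Gaussian displacement (nm, >= 0) applied to
#'   each particle from its generating structure; default 10 nm, on the
#'   order of the antibody-gold offset for 12 nm colloidal gold.
#' @param dilutions character labels of the dilution series; scenes cycle
#'   through them.
#' @param controlFraction fraction of additional control micrographs
#'   generated (relative to \code{nMicrographs}).
#' @param backgroundMax maximum background particles on a control scene.
#' @param seed integer seed.
#' @return a \code{GoldDesign} list.
#' @examples
#' goldDesign(c(plasma_membrane = 0.21, cisternae = 0.67, flagellum = 0.12),
#'            nParticles = 100, nMicrographs = 6, seed = 1)
#' @export
goldDesign <- function(compartmentFractions, nParticles, nMicrographs,
                       jitterSd = 10, dilutions = c("1:1", "1:5", "1:10"),
                       controlFraction = 0.1, backgroundMax = 5L,
                       seed = 1L) {
  want <- c("plasma_membrane", "cisternae", "flagellum")
  if (!is.numeric(compartmentFractions) ||
      !setequal(names(compartmentFractions), want) ||
      any(compartmentFractions < 0) ||
      abs(sum(compartmentFractions) - 1) > 1e-9)
    stop("'compartmentFractions' must be named proportions over ",
         paste(want, collapse = ", "), " summing to 1", call. = FALSE)
  .assertScalarNumber(nParticles, "nParticles", lower = 1)
  .assertScalarNumber(nMicrographs, "nMicrographs", lower = 1)
  .assertScalarNumber(jitterSd, "jitterSd", lower = 0)
  .assertScalarNumber(controlFraction, "controlFraction", 0, 1)
  .assertScalarNumber(backgroundMax, "backgroundMax", lower = 0)
  structure(list(compartmentFractions = compartmentFractions[want],
                 nParticles = as.integer(nParticles),
                 nMicrographs = as.integer(nMicrographs),
                 jitterSd = jitterSd, dilutions = dilutions,
                 controlFraction = controlFraction,
                 backgroundMax = as.integer(backgroundMax),
                 seed = as.integer(seed)),
            class = "GoldDesign")
}

# canonical scene geometry (nm, image convention): a Hermes-body profile
# bounded by a closed plasma membrane, three internal cisterna traces, and
# a separate flagellum cross-section; clearances between structures are
# large relative to the 36 nm reference band plus jitter.
.sceneGeometry <- function(sectionKind) {
  th <- seq(0, 2 * pi, length.out = 61L)[-61L]
  pm <- cbind(1000 + 900 * cos(th), 800 + 600 * sin(th))
  cis <- lapply(c(550, 800, 1050), function(y) {
    x <- seq(450, 1550, length.out = 23L)
    cbind(x, y + 40 * sin((x - 450) / 1100 * pi))
  })
  thf <- seq(0, 2 * pi, length.out = 31L)[-31L]
  fl <- cbind(2700 + 250 * cos(thf), 800 + 250 * sin(thf))
  c(list(list(compartment = "plasma_membrane", sectionKind = sectionKind,
              closed = TRUE, coords = pm)),
    lapply(cis, function(m) list(compartment = "cisterna",
                                 sectionKind = "cross", closed = FALSE,
                                 coords = unname(m))),
    list(list(compartment = "flagellum", sectionKind = sectionKind,
              closed = TRUE, coords = fl)))
}

# cumulative-length uniform sampling of points on a polyline
.samplePolylinePoints <- function(coords, n, closed) {
  if (closed) coords <- rbind(coords, coords[1L, , drop = FALSE])
  d <- sqrt(rowSums(diff(coords)^2))
  cs <- c(0, cumsum(d))
  t <- stats::runif(n, 0, cs[length(cs)])
  seg <- findInterval(t, cs, rightmost.closed = TRUE)
  seg[seg >= length(cs)] <- length(cs) - 1L
  frac <- (t - cs[seg]) / d[seg]
  coords[seg, , drop = FALSE] +
    frac * (coords[seg + 1L, , drop = FALSE] - coords[seg, , drop = FALSE])
}

#' Generate synthetic immunogold scenes
#'
#' Produces \linkS4class{GoldScene} objects with a known ground truth: each
#' particle is placed uniformly along a structure chosen by the design's
#' compartment proportions, then displaced by isotropic Gaussian jitter,
#' and keeps its generating compartment as a truth label. Control scenes
#' (no primary antibody) carry only a small background particle count and
#' no truth labels. Scenes alternate between two animals, cycle through
#' the dilution series, and alternate cross/oblique section kinds.
#'
#' @param design a \code{GoldDesign} from [goldDesign()].
#' @return list of \linkS4class{GoldScene} objects (labelled scenes first,
#'   then controls).
#' @export
generateGoldScenes <- function(design) {
  stopifnot(inherits(design, "GoldDesign"))
  comps <- names(design$compartmentFractions)
  nCtrl <- round(design$controlFraction * design$nMicrographs)
  scenes <- vector("list", design$nMicrographs + nCtrl)
  for (i in seq_len(design$nMicrographs)) {
    set.seed(childSeed(design$seed, paste0("scene:", i)))
    kind <- if (i %% 2L == 1L) "cross" else "oblique"
    structures <- .sceneGeometry(kind)
    structComp <- vapply(structures, `[[`, character(1), "compartment")
    lab <- sample(comps, design$nParticles, replace = TRUE,
                  prob = design$compartmentFractions)
    pts <- matrix(0, design$nParticles, 2L)
    for (cmp in comps) {
      idx <- which(lab == cmp)
      if (!length(idx)) next
      # cisterna particles spread over the available cisterna traces
      cand <- which(structComp == switch(cmp, cisternae = "cisterna", cmp))
      pick <- cand[sample.int(length(cand), length(idx), replace = TRUE)]
      for (j in seq_along(idx)) {
        st <- structures[[pick[j]]]
        pts[idx[j], ] <- .samplePolylinePoints(st$coords, 1L, st$closed)
      }
    }
    pts <- pts + matrix(stats::rnorm(2L * design$nParticles, 0,
                                     design$jitterSd),
                        ncol = 2L)
    scenes[[i]] <- new("GoldScene",
      sceneId = sprintf("mg%03d", i),
      animal = if (i %% 2L == 1L) "animal1" else "animal2",
      dilution = design$dilutions[((i - 1L) %% length(design$dilutions)) + 1L],
      isControl = FALSE, structures = structures,
      particles = data.frame(x = pts[, 1L], y = pts[, 2L], truth = lab,
                             stringsAsFactors = FALSE))
  }
  for (k in seq_len(nCtrl)) {
    i <- design$nMicrographs + k
    set.seed(childSeed(design$seed, paste0("control:", k)))
    nb <- min(design$backgroundMax,
              stats::rpois(1L, design$backgroundMax / 2))
    scenes[[i]] <- new("GoldScene",
      sceneId = sprintf("ctrl%03d", k),
      animal = if (k %% 2L == 1L) "animal1" else "animal2",
      dilution = design$dilutions[((k - 1L) %% length(design$dilutions)) + 1L],
      isControl = TRUE, structures = .sceneGeometry("cross"),
      particles = data.frame(x = stats::runif(nb, 0, 3000),
                             y = stats::runif(nb, 0, 1600),
                             truth = rep(NA_character_, nb),
                             stringsAsFactors = FALSE))
  }
  scenes
}
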