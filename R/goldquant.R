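#' @name goldquant
#' @title Immunogold particle quantification around membrane traces
#' @description
#' Quantifies colloidal-gold particle distributions on electron micrograph
#' scenes: signed Euclidean distances from particles to membrane
#' polylines, fixed-increment band histograms on either side of the plasma
#' membrane, derivation of the reference band (the symmetric span holding
#' most membrane-proximal particles), five-area classification of every
#' particle (cross/oblique plasma membrane, intracytoplasmic cisternae,
#' cross/oblique flagellum), and aggregation into percentage distributions
#' with mean and s.d. across aggregation units. Control scenes are
#' summarized separately and never pooled with labelled scenes.
NULL

# minimum distance from each point (n x 2) to a polyline; returns the
# unsigned distance. Loops over segments with vectorized point arithmetic.
.polylineDistance <- function(points, coords, closed = FALSE) {
  if (closed) coords <- rbind(coords, coords[1L, , drop = FALSE])
  nseg <- nrow(coords) - 1L
  if (nseg < 1L) stop("degenerate polyline: fewer than 2 vertices",
                      call. = FALSE)
  px <- points[, 1L]; py <- points[, 2L]
  best <- rep(Inf, length(px))
  for (i in seq_len(nseg)) {
    ax <- coords[i, 1L]; ay <- coords[i, 2L]
    bx <- coords[i + 1L, 1L]; by <- coords[i + 1L, 2L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
      d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# even-odd rule point-in-polygon (polygon given open; closure implied)
.pointInPolygon <- function(points, coords) {
  n <- nrow(coords)
  px <- points[, 1L]; py <- points[, 2L]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1L]; yi <- coords[i, 2L]
    xj <- coords[j, 1L]; yj <- coords[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Signed distance from points to a membrane structure
#'
#' Euclidean distance from each point to the nearest segment of the
#' structure's polyline. For closed polylines the distance is signed:
#' negative on the enclosed (intracellular) side, positive outside. Open
#' polylines yield unsigned (positive) distances, the side being undefined
#' for an unclosed trace.
#'
#' @param points numeric n x 2 matrix of nm coordinates (a single point
#'   may be given as a length-2 vector).
#' @param structure a structure list as held by a
#'   \linkS4class{GoldScene}: elements \code{coords} (matrix) and
#'   \code{closed} (logical).
#' @return numeric vector of signed distances (nm).
#' @examples
#' sq <- list(coords = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
#'            closed = TRUE)
#' distanceToStructure(rbind(c(5, 5), c(5, -3)), sq)
#' @export
distanceToStructure <- function(points, structure) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  stopifnot(ncol(points) == 2L)
  coords <- structure$coords
  if (!is.matrix(coords) || nrow(coords) < 2L)
    stop("degenerate polyline: fewer than 2 vertices", call. = FALSE)
  if (all(apply(coords, 2L, function(v) diff(range(v)) == 0)))
    stop("degenerate polyline: zero length", call. = FALSE)
  d <- .polylineDistance(points, coords, closed = isTRUE(structure$closed))
  if (isTRUE(structure$closed)) {
    inside <- .pointInPolygon(points, coords)
    d[inside] <- -d[inside]
  }
  d
}

#' Band histogram of gold particles around the plasma membrane
#'
#' Bins every particle within the maximum scored span by its signed
#' distance to the scene's plasma membrane into increments of fixed width.
#' Bin edges sit at integer multiples of the increment, each bin half-open
#' \code{[k*w, (k+1)*w)}; negative offsets are intracellular, positive
#' extracellular. With multiple plasma-membrane structures, the signed
#' distance of smallest magnitude is used.
#'
#' @param scene a \linkS4class{GoldScene} with a plasma_membrane structure.
#' @param increment bin width in nm (default 12, the colloidal-gold
#'   particle diameter).
#' @param maxSpan maximum |signed distance| scored, nm (default 120).
#' @return a \code{BandHistogram}: list with \code{increment},
#'   \code{bins} (integer counts named by lower bin edge), \code{nScored}
#'   and \code{nTotal}.
#' @export
bandHistogram <- function(scene, increment = 12, maxSpan = 120) {
  stopifnot(is(scene, "GoldScene"))
  .assertScalarNumber(increment, "increment", lower = 1e-9)
  pm <- Filter(function(s) s$compartment == "plasma_membrane",
               scene@structures)
  if (!length(pm))
    stop("scene has no plasma_membrane structure", call. = FALSE)
  p <- sceneParticles(scene)
  pts <- cbind(p$x, p$y)
  if (nrow(pts) == 0L) {
    d <- numeric(0)
  } else {
    dAll <- vapply(pm, function(s) distanceToStructure(pts, s),
                   numeric(nrow(pts)))
    dAll <- matrix(dAll, nrow = nrow(pts))
    d <- dAll[cbind(seq_len(nrow(pts)), max.col(-abs(dAll), "first"))]
  }
  keep <- abs(d) <= maxSpan
  k <- floor(d[keep] / increment)
  kmax <- ceiling(maxSpan / increment)
  lev <- seq.int(-kmax, kmax - 1L)
  bins <- table(factor(k, levels = lev))
  bins <- stats::setNames(as.integer(bins), as.character(lev * increment))
  structure(list(increment = increment, bins = bins,
                 nScored = sum(keep), nTotal = nrow(pts)),
            class = "BandHistogram")
}

#' @export
print.BandHistogram <- function(x, ...) {
  cat(sprintf("BandHistogram: %d nm increments, %d of %d particle(s) scored\n",
              x$increment, x$nScored, x$nTotal))
  print(x$bins)
  invisible(x)
}

#' Derive the reference band from a band histogram
#'
#' Finds the smallest symmetric span around the membrane, in whole
#' increments, whose bins contain at least the requested coverage of all
#' scored membrane-proximal particles. The returned half-width times two
#' is the reference span used to attribute particles to a membrane (72 nm
#' for the default 12 nm increments when three increments per side
#' suffice).
#'
#' @param histogram a \code{BandHistogram}.
#' @param coverage required fraction of scored particles inside the band
#'   (default 0.95).
#' @return band half-width in nm (a multiple of the increment).
#' @export
referenceBand <- function(histogram, coverage = 0.95) {
  stopifnot(inherits(histogram, "BandHistogram"))
  .assertScalarNumber(coverage, "coverage", lower = 0, upper = 1)
  total <- sum(histogram$bins)
  if (total == 0L) stop("empty histogram", call. = FALSE)
  w <- histogram$increment
  edges <- as.numeric(names(histogram$bins))
  kmax <- max(abs(edges)) / w
  for (k in seq_len(kmax)) {
    inBand <- edges >= -k * w & edges < k * w
    if (sum(histogram$bins[inBand]) >= coverage * total) return(k * w)
  }
  kmax * w
}

#' Classify every particle of a scene into the five scoring areas
#'
#' A particle lying within the reference band of one or more structures is
#' attributed to the nearest such structure (ties favour the plasma
#' membrane); its zone combines the structure's compartment and section
#' kind: \code{plasma_membrane_cross}, \code{plasma_membrane_oblique},
#' \code{intracytoplasmic} (cisternae), \code{flagellum_cross},
#' \code{flagellum_oblique}. Particles inside the plasma membrane but
#' within no band default to \code{intracytoplasmic}; particles outside
#' the cell and all bands are \code{unassigned} and excluded from
#' distributions.
#'
#' @param scene a \linkS4class{GoldScene}.
#' @param bandHalfWidth reference band half-width, nm (> 0; default 36,
#'   i.e. a 72 nm span).
#' @return data.frame with one row per particle: \code{x}, \code{y},
#'   \code{zone}, \code{compartment} (\code{plasma_membrane},
#'   \code{cisternae}, \code{flagellum} or \code{unassigned}),
#'   \code{distanceNm} (distance to the assigned structure, NA when
#'   unassigned or defaulted), and \code{truth}.
#' @export
classifyParticles <- function(scene, bandHalfWidth = 36) {
  stopifnot(is(scene, "GoldScene"))
  .assertScalarNumber(bandHalfWidth, "bandHalfWidth", lower = 1e-12)
  p <- sceneParticles(scene)
  n <- nrow(p)
  structures <- scene@structures
  comp <- vapply(structures, `[[`, character(1), "compartment")
  kind <- vapply(structures, `[[`, character(1), "sectionKind")
  out <- data.frame(x = p$x, y = p$y, zone = rep("unassigned", n),
                    compartment = rep("unassigned", n),
                    distanceNm = rep(NA_real_, n), truth = p$truth,
                    stringsAsFactors = FALSE)
  if (n == 0L || length(structures) == 0L) return(out)
  pts <- cbind(p$x, p$y)
  dm <- vapply(structures, function(s) distanceToStructure(pts, s),
               numeric(n))
  dm <- matrix(dm, nrow = n)
  adm <- abs(dm)
  insidePM <- rep(FALSE, n)
  for (j in which(comp == "plasma_membrane" &
                  vapply(structures, function(s) isTRUE(s$closed),
                         logical(1))))
    insidePM <- insidePM | (dm[, j] < 0)
  for (i in seq_len(n)) {
    within <- which(adm[i, ] <= bandHalfWidth)
    if (length(within)) {
      dmin <- min(adm[i, within])
      cand <- within[adm[i, within] == dmin]
      j <- if (any(comp[cand] == "plasma_membrane"))
        cand[comp[cand] == "plasma_membrane"][1L] else cand[1L]
      out$compartment[i] <- switch(comp[j], cisterna = "cisternae", comp[j])
      out$zone[i] <- if (comp[j] == "cisterna") "intracytoplasmic"
        else paste(comp[j], kind[j], sep = "_")
      out$distanceNm[i] <- dmin
    } else if (insidePM[i]) {
      out$compartment[i] <- "cisternae"
      out$zone[i] <- "intracytoplasmic"
    }
  }
  out
}

#' Aggregate classified particles into zonal percentage distributions
#'
#' Classifies every scene, collapses the five scoring areas to the three
#' reporting compartments (plasma membrane, intracytoplasmic cisternae,
#' flagellum), pools counts within each aggregation unit, converts to
#' percentages, and reports mean and sample s.d. of the percentages across
#' units. Every particle counts once (clustered particles are individual
#' rows in the scene). Control scenes are summarized separately and never
#' pooled with labelled scenes.
#'
#' @param scenes list of \linkS4class{GoldScene} objects.
#' @param bandHalfWidth reference band half-width in nm (default 36).
#' @param by aggregation unit: \code{"dilution"} (default),
#'   \code{"animal"} or \code{"scene"}.
#' @return a \code{ZoneDistribution}: list with \code{perUnit}
#'   (unit x compartment counts and percentages), \code{summary}
#'   (per-compartment mean/s.d. of percentages across units, with
#'   \code{nUnits}), \code{zoneCounts} (pooled five-area counts),
#'   \code{nParticles} (assigned particles), \code{nUnassigned}, and
#'   \code{controls} (per-control-scene particle counts).
#' @export
zoneDistribution <- function(scenes, bandHalfWidth = 36,
                             by = c("dilution", "animal", "scene")) {
  by <- match.arg(by)
  stopifnot(is.list(scenes), length(scenes) > 0L)
  ctrl <- vapply(scenes, isControl, logical(1))
  if (!any(!ctrl)) stop("no non-control scene supplied", call. = FALSE)
  compLevels <- c("plasma_membrane", "intracytoplasmic_cisternae",
                  "flagellum")
  zoneLevels <- c("plasma_membrane_cross", "plasma_membrane_oblique",
                  "intracytoplasmic", "flagellum_cross",
                  "flagellum_oblique")
  rows <- list()
  zoneCounts <- stats::setNames(integer(length(zoneLevels)), zoneLevels)
  nUn <- 0L
  for (sc in scenes[!ctrl]) {
    cls <- classifyParticles(sc, bandHalfWidth)
    unit <- switch(by, dilution = sc@dilution, animal = sc@animal,
                   scene = sc@sceneId)
    keep <- cls$compartment != "unassigned"
    nUn <- nUn + sum(!keep)
    zc <- table(factor(cls$zone[keep], levels = zoneLevels))
    zoneCounts <- zoneCounts + as.integer(zc)
    cmp <- ifelse(cls$compartment[keep] == "cisternae",
                  "intracytoplasmic_cisternae", cls$compartment[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      unit = rep(unit, sum(keep)), compartment = cmp,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0L)
    stop("no particles in any non-control scene", call. = FALSE)
  tab <- table(factor(all$unit), factor(all$compartment,
                                        levels = compLevels))
  perUnit <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(perUnit) <- c("unit", "compartment", "count")
  totals <- stats::setNames(rowSums(tab), rownames(tab))
  perUnit$percent <- 100 * perUnit$count / totals[perUnit$unit]
  perUnit <- perUnit[order(perUnit$unit,
                           match(perUnit$compartment, compLevels)), ]
  rownames(perUnit) <- NULL
  pctMat <- matrix(perUnit$percent, nrow = length(compLevels),
                   dimnames = list(compLevels, NULL))
  summary <- data.frame(
    compartment = compLevels,
    meanPercent = rowMeans(pctMat),
    sdPercent = if (ncol(pctMat) > 1L) apply(pctMat, 1L, stats::sd)
      else rep(0, length(compLevels)),
    nUnits = ncol(pctMat), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  controls <- data.frame(
    sceneId = vapply(scenes[ctrl], function(s) s@sceneId, character(1)),
    nParticles = vapply(scenes[ctrl],
                        function(s) nrow(sceneParticles(s)), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(perUnit = perUnit, summary = summary,
                 zoneCounts = zoneCounts, nParticles = nrow(all),
                 nUnassigned = nUn, controls = controls,
                 bandHalfWidth = bandHalfWidth, by = by),
            class = "ZoneDistribution")
}

#' @export
print.ZoneDistribution <- function(x, ...) {
  cat(sprintf(
    "ZoneDistribution: %d particle(s) over %d unit(s) (by %s), band %g nm\n",
    x$nParticles, x$summary$nUnits[1L], x$by, x$bandHalfWidth))
  with(x$summary, cat(sprintf("  %-28s %5.1f +/- %4.1f %%\n", compartment,
                              meanPercent, sdPercent), sep = ""))
  if (x$nUnassigned) cat(sprintf("  %d particle(s) unassigned/excluded\n",
                                 x$nUnassigned))
  if (nrow(x$controls))
    cat(sprintf("  %d control scene(s), %d background particle(s) total\n",
                nrow(x$controls), sum(x$controls$nParticles)))
  invisible(x)
}

#' Pool band histograms from several scenes
#'
#' Sums the bin counts of histograms computed with identical increments,
#' e.g. to derive one reference band from a set of micrographs.
#'
#' @param histograms list of \code{BandHistogram} objects.
#' @return a pooled \code{BandHistogram}.
#' @export
poolBandHistograms <- function(histograms) {
  stopifnot(length(histograms) >= 1L,
            all(vapply(histograms, inherits, logical(1),
                       "BandHistogram")))
  inc <- unique(vapply(histograms, `[[`, numeric(1), "increment"))
  if (length(inc) != 1L)
    stop("histograms use different increments", call. = FALSE)
  edges <- names(histograms[[1L]]$bins)
  bins <- Reduce(`+`, lapply(histograms, function(h) h$bins[edges]))
  structure(list(increment = inc, bins = bins,
                 nScored = sum(vapply(histograms, `[[`, numeric(1),
                                      "nScored")),
                 nTotal = sum(vapply(histograms, `[[`, numeric(1),
                                     "nTotal"))),
            class = "BandHistogram")
}
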