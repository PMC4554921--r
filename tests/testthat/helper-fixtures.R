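# shared fixtures and independent oracles, built in code

# the worked three-protein toy: P1 = {a,b,c}, P2 = {c,d}, P3 = {c}
toyMap <- function() {
  new("PeptideProteinMap",
      map = list(a = "P1", b = "P1", c = c("P1", "P2", "P3"), d = "P2"),
      orphans = character(0))
}

# random peptide-protein instance for cover tests
randomInstance <- function(nProteins = sample(4:12, 1),
                           nPeptides = sample(6:18, 1)) {
  prot <- sprintf("P%02d", seq_len(nProteins))
  map <- lapply(seq_len(nPeptides), function(j)
    sort(sample(prot, 1L + stats::rbinom(1L, 3L, 0.25))))
  names(map) <- sprintf("pep%02d", seq_len(nPeptides))
  new("PeptideProteinMap", map = map, orphans = character(0))
}

# exhaustive minimum-cover oracle: enumerate subsets of the deduplicated
# candidate peptide sets, smallest first
bruteMinCoverSize <- function(map) {
  m <- peptideMap(map)
  sets <- split(rep(names(m), lengths(m)), unlist(m))
  sets <- lapply(sets, sort)
  sets <- sets[!duplicated(sets)]
  universe <- names(m)
  for (k in seq_along(sets)) {
    for (cmb in utils::combn(length(sets), k, simplify = FALSE))
      if (all(universe %in% unlist(sets[cmb]))) return(k)
  }
  length(sets)
}

# brute-force point-to-polyline distance: per-segment minimization
bruteSegmentDistance <- function(pt, coords, closed = FALSE) {
  if (closed) coords <- rbind(coords, coords[1, , drop = FALSE])
  best <- Inf
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    best <- min(best, sqrt(sum((pt - (a + t * ab))^2)))
  }
  best
}

# a minimal hand-built scene: a 1000x1000 nm square plasma membrane, one
# horizontal cisterna trace inside, one square flagellum outside
simpleScene <- function(particles, sceneId = "s1", dilution = "1:5",
                        isControl = FALSE) {
  pm <- list(compartment = "plasma_membrane", sectionKind = "cross",
             closed = TRUE,
             coords = rbind(c(0, 0), c(1000, 0), c(1000, 1000),
                            c(0, 1000)))
  cis <- list(compartment = "cisterna", sectionKind = "cross",
              closed = FALSE, coords = rbind(c(200, 500), c(800, 500)))
  fl <- list(compartment = "flagellum", sectionKind = "oblique",
             closed = TRUE,
             coords = rbind(c(2000, 0), c(2400, 0), c(2400, 400),
                            c(2000, 400)))
  new("GoldScene", sceneId = sceneId, animal = "animal1",
      dilution = dilution, isControl = isControl,
      structures = list(pm, cis, fl), particles = particles)
}

particleFrame <- function(x, y, truth = NA_character_) {
  data.frame(x = x, y = y, truth = rep_len(truth, length(x)),
             stringsAsFactors = FALSE)
}

# PSM rows for constructed quantification cases
psmRows <- function(peptide, n, sample = "F1", replicate = 1L) {
  data.frame(peptide = rep(peptide, n), sample = rep(sample, n),
             replicate = rep(replicate, n),
             confidence = rep(0.99, n), stringsAsFactors = FALSE)
}
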