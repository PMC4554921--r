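#' Map peptides onto a protein database
#'
#' Assigns each peptide to every database protein whose sequence contains
#' it as an exact substring. Peptides matching no protein are returned as
#' orphans (reported with a message, excluded downstream); on a complete
#' database the search engine cannot produce them, but toy databases can.
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally).
#' @param database a named character vector or
#'   \link[Biostrings]{AAStringSet} of protein sequences, names =
#'   accessions.
#' @param equateIL treat I and L as indistinguishable (as many search
#'   engines do); default \code{FALSE}.
#' @return a \linkS4class{PeptideProteinMap}.
#' @examples
#' db <- c(P1 = "AAAKCCCK", P2 = "AAAK")
#' peptideMap(mapPeptides(c("AAAK", "CCCK"), db))
#' @export
mapPeptides <- function(peptides, database, equateIL = FALSE) {
  if (is(database, "XStringSet"))
    database <- stats::setNames(as.character(database), names(database))
  if (length(database) == 0L || is.null(names(database)))
    stop("'database' must be non-empty and named by accession",
         call. = FALSE)
  peptides <- unique(as.character(peptides))
  seqs <- database
  pp <- peptides
  if (equateIL) {
    seqs <- chartr("I", "L", seqs)
    pp <- chartr("I", "L", pp)
  }
  acc <- names(database)
  hits <- lapply(pp, function(p) acc[vapply(
    seqs, function(s) grepl(p, s, fixed = TRUE), logical(1))])
  names(hits) <- peptides
  orphan <- lengths(hits) == 0L
  if (any(orphan))
    message(sum(orphan), " orphan peptide(s) matched no database protein")
  new("PeptideProteinMap", map = hits[!orphan],
      orphans = peptides[orphan])
}

#' Infer the minimal set of protein groups
#'
#' Collapses redundant identifications into the minimum set of protein
#' groups that explains all mapped peptides, in three phases:
#' \enumerate{
#'   \item proteins with identical matched-peptide sets merge into one
#'     group (representative = lexicographically smallest accession);
#'   \item a protein whose peptide set is a strict subset of another
#'     remaining protein's set is absorbed as a member of that protein's
#'     group (among several supersets, the one sharing the most peptides
#'     wins; ties go to the lexicographically smallest representative);
#'   \item remaining groups enter a minimum set cover: greedy selection
#'     (the group explaining the most not-yet-covered peptides is retained
#'     repeatedly until all peptides are covered; ties: most total
#'     peptides, then smallest representative accession), followed by
#'     pruning of retained groups whose peptides the other retained groups
#'     already cover; when at most 15 candidate groups remain after
#'     absorption, an exhaustive search certifies the cover is a true
#'     minimum (lexicographically smallest among minima).
#' }
#' After selection, peptides are re-labelled unique or shared with respect
#' to the retained groups only. All tie-breaks are lexicographic, so the
#' result does not depend on database order.
#'
#' @param map a \linkS4class{PeptideProteinMap} from [mapPeptides()].
#' @return a \linkS4class{ProteinGroupSet} ordered by representative
#'   accession.
#' @examples
#' m <- new("PeptideProteinMap",
#'          map = list(a = "P1", b = "P1", c = c("P1", "P2", "P3"),
#'                     d = "P2"),
#'          orphans = character(0))
#' inferMinimalSet(m)
#' @export
inferMinimalSet <- function(map) {
  stopifnot(is(map, "PeptideProteinMap"))
  pmap <- peptideMap(map)
  if (length(pmap) == 0L) stop("empty peptide map", call. = FALSE)
  # invert: protein -> sorted peptide set
  prot <- sort(unique(unlist(pmap)))
  protPeps <- lapply(prot, function(a) {
    sort(names(pmap)[vapply(pmap, function(v) a %in% v, logical(1))])
  })
  names(protPeps) <- prot

  # phase 1: identical evidence
  sig <- vapply(protPeps, paste, character(1), collapse = "\r")
  groups <- lapply(split(prot, sig), sort)
  reps <- vapply(groups, `[`, character(1), 1L)
  peps <- protPeps[reps]
  names(groups) <- names(peps) <- reps
  ord <- order(reps)
  groups <- groups[ord]; peps <- peps[ord]; reps <- reps[ord]

  # phase 2: absorb strict subsets, smallest evidence first
  repeat {
    sizes <- lengths(peps)
    absorbed <- FALSE
    for (g in names(peps)[order(sizes, names(peps))]) {
      sup <- names(peps)[vapply(names(peps), function(h) {
        h != g && length(peps[[g]]) < length(peps[[h]]) &&
          all(peps[[g]] %in% peps[[h]])
      }, logical(1))]
      if (length(sup)) {
        # all supersets share the full subset; tie-break lexicographically
        shared <- vapply(sup,
                         function(h) length(intersect(peps[[g]], peps[[h]])),
                         integer(1))
        target <- sort(sup[shared == max(shared)])[1L]
        groups[[target]] <- sort(union(groups[[target]], groups[[g]]))
        groups[[g]] <- NULL; peps[[g]] <- NULL
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) break
  }

  # phase 3: minimum cover. Greedy (most uncovered peptides, then most
  # total, then smallest accession) gives the initial solution; retained
  # groups made redundant by the others are then pruned; for small pools
  # an exhaustive iterative-deepening search certifies minimality.
  allPeps <- names(pmap)
  uncovered <- allPeps
  retained <- character(0)
  pool <- sort(names(peps))
  avail <- pool
  while (length(uncovered)) {
    gain <- vapply(avail, function(g) sum(peps[[g]] %in% uncovered),
                   integer(1))
    cand <- avail[gain == max(gain)]
    if (length(cand) > 1L) {
      tot <- lengths(peps[cand])
      cand <- cand[tot == max(tot)]
    }
    pick <- sort(cand)[1L]
    retained <- c(retained, pick)
    uncovered <- setdiff(uncovered, peps[[pick]])
    avail <- setdiff(avail, pick)
  }
  repeat {  # prune groups covered by the rest, smallest evidence first
    drop <- NULL
    for (g in retained[order(lengths(peps[retained]), retained)]) {
      if (all(peps[[g]] %in% unlist(peps[setdiff(retained, g)]))) {
        drop <- g; break
      }
    }
    if (is.null(drop)) break
    retained <- setdiff(retained, drop)
  }
  if (length(pool) <= 15L && length(retained) > 1L) {
    found <- NULL
    for (k in seq_len(length(retained) - 1L)) {
      for (cmb in utils::combn(pool, k, simplify = FALSE)) {
        if (all(allPeps %in% unlist(peps[cmb]))) { found <- cmb; break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) retained <- found
  }
  retained <- sort(retained)

  # re-label unique/shared w.r.t. retained groups only
  memberOf <- groups[retained]
  uniq <- shar <- stats::setNames(vector("list", length(retained)),
                                  retained)
  for (g in retained) uniq[[g]] <- shar[[g]] <- character(0)
  for (p in allPeps) {
    holders <- retained[vapply(retained, function(g)
      any(memberOf[[g]] %in% pmap[[p]]), logical(1))]
    if (length(holders) == 1L)
      uniq[[holders]] <- c(uniq[[holders]], p)
    else for (g in holders) shar[[g]] <- c(shar[[g]], p)
  }
  new("ProteinGroupSet",
      representative = retained,
      members = unname(memberOf),
      uniquePeptides = lapply(unname(uniq[retained]), sort),
      sharedPeptides = lapply(unname(shar[retained]), sort),
      orphans = orphanPeptides(map))
}

#' Classify peptides as unique or shared across retained groups
#'
#' @param groups a \linkS4class{ProteinGroupSet}.
#' @return named list: peptide -> character vector of the representative
#'   accessions of the retained groups containing it (length 1 = unique).
#' @export
classifyPeptides <- function(groups) {
  stopifnot(is(groups, "ProteinGroupSet"))
  out <- list()
  reps <- representatives(groups)
  for (i in seq_along(reps)) {
    for (p in groups@uniquePeptides[[i]]) out[[p]] <- reps[i]
    for (p in groups@sharedPeptides[[i]])
      out[[p]] <- sort(c(out[[p]], reps[i]))
  }
  out
}
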