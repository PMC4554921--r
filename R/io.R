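#' Read a protein FASTA database
#'
#' Accessions are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate accessions and empty records are
#' format errors.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names = accessions), in
#'   file order.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(aa) == 0L))
    stop("empty FASTA record(s): ",
         paste(acc[Biostrings::width(aa) == 0L], collapse = ", "),
         call. = FALSE)
  stats::setNames(toupper(as.character(aa)), acc)
}

#' Write a proteome to FASTA
#'
#' @param proteome a \code{GroundTruthProteome}, named character vector or
#'   \link[Biostrings]{AAStringSet}.
#' @param path output path.
#' @export
writeProteinFasta <- function(proteome, path) {
  if (inherits(proteome, "GroundTruthProteome"))
    proteome <- proteome$proteins
  if (!is(proteome, "XStringSet"))
    proteome <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' Read a PSM table and filter on confidence
#'
#' Tab-separated, UTF-8, \code{"."} decimal, no quoting; required columns
#' \code{peptide}, \code{sample}, \code{replicate}, \code{confidence}
#' (one row per spectrum). Rows below the confidence threshold are
#' dropped and the dropped count reported (message and attribute).
#'
#' @param path file path.
#' @param minConfidence acceptance threshold in [0, 1]; default 0.95, the
#'   conventional assignment confidence.
#' @return data.frame of retained PSM records, with attribute
#'   \code{"dropped"} = number of rows removed by the filter.
#' @export
readPSMTable <- function(path, minConfidence = 0.95) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .assertScalarNumber(minConfidence, "minConfidence", 0, 1)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("peptide", "sample", "replicate", "confidence")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) {
    warning("PSM table has a header but no rows: ", path, call. = FALSE)
    out <- data.frame(peptide = character(0), sample = character(0),
                      replicate = integer(0), confidence = numeric(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  conf <- suppressWarnings(as.numeric(df$confidence))
  if (anyNA(conf))
    stop("non-numeric confidence at line(s) ",
         paste(utils::head(which(is.na(conf)) + 1L, 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  repl <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(repl))
    stop("non-integer replicate at line(s) ",
         paste(utils::head(which(is.na(repl)) + 1L, 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  keep <- conf >= minConfidence
  if (any(!keep))
    message(sum(!keep), " PSM(s) dropped below confidence ",
            format(minConfidence))
  out <- data.frame(peptide = df$peptide[keep], sample = df$sample[keep],
                    replicate = repl[keep], confidence = conf[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Write a PSM table
#'
#' @param psms data.frame with columns \code{peptide}, \code{sample},
#'   \code{replicate}, \code{confidence}.
#' @param path output path.
#' @export
writePSMTable <- function(psms, path) {
  utils::write.table(
    psms[, c("peptide", "sample", "replicate", "confidence")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gold scenes as JSON
#'
#' Scene files are JSON with fields \code{scene_id}, \code{animal},
#' \code{dilution}, \code{is_control}, \code{coordinate_convention}
#' (nanometres, origin top-left, y increasing downward),
#' \code{structures} (each with \code{compartment}, \code{section_kind},
#' \code{closed} and \code{coords}, an ordered list of [x, y] nm pairs)
#' and \code{particles} (objects with \code{x}, \code{y} and optional
#' \code{truth}). Writing then reading returns an equal scene.
#'
#' @param path file path.
#' @return [readGoldScene()]: a \linkS4class{GoldScene}.
#' @export
readGoldScene <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed scene JSON in ", path,
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  for (f in c("scene_id", "animal", "dilution", "is_control",
              "structures", "particles"))
    if (is.null(j[[f]]))
      stop("scene JSON missing field '", f, "' in ", path, call. = FALSE)
  structures <- lapply(seq_along(j$structures), function(i) {
    s <- j$structures[[i]]
    for (f in c("compartment", "section_kind", "closed", "coords"))
      if (is.null(s[[f]]))
        stop("structure ", i, " missing '", f, "' in ", path,
             call. = FALSE)
    coords <- do.call(rbind, lapply(s$coords, function(xy)
      c(as.numeric(xy[[1]]), as.numeric(xy[[2]]))))
    list(compartment = s$compartment, sectionKind = s$section_kind,
         closed = isTRUE(s$closed), coords = coords)
  })
  particles <- if (length(j$particles)) {
    data.frame(
      x = vapply(j$particles, function(p) as.numeric(p$x), numeric(1)),
      y = vapply(j$particles, function(p) as.numeric(p$y), numeric(1)),
      truth = vapply(j$particles, function(p)
        if (is.null(p$truth)) NA_character_ else as.character(p$truth),
        character(1)),
      stringsAsFactors = FALSE)
  } else data.frame(x = numeric(0), y = numeric(0),
                    truth = character(0), stringsAsFactors = FALSE)
  new("GoldScene", sceneId = j$scene_id, animal = j$animal,
      dilution = j$dilution, isControl = isTRUE(j$is_control),
      structures = structures, particles = particles)
}

#' @rdname readGoldScene
#' @param scene a \linkS4class{GoldScene}.
#' @export
writeGoldScene <- function(scene, path) {
  stopifnot(is(scene, "GoldScene"))
  p <- sceneParticles(scene)
  particles <- lapply(seq_len(nrow(p)), function(i) {
    rec <- list(x = p$x[i], y = p$y[i])
    if (!is.na(p$truth[i])) rec$truth <- p$truth[i]
    rec
  })
  j <- list(
    scene_id = scene@sceneId, animal = scene@animal,
    dilution = scene@dilution, is_control = scene@isControl,
    coordinate_convention = "nm; origin top-left; y increases downward",
    structures = lapply(scene@structures, function(s) list(
      compartment = s$compartment, section_kind = s$sectionKind,
      closed = s$closed,
      coords = lapply(seq_len(nrow(s$coords)),
                      function(i) as.numeric(s$coords[i, ])))),
    particles = particles)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a quantification matrix as TSV
#'
#' One row per protein group, one column per sample; tab-separated with a
#' leading \code{accession} column. Reading a written file returns the
#' identical matrix.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @export
writeMatrixTSV <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"accession" %in% colnames(df))
    stop("matrix TSV missing 'accession' column: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "accession"), drop = FALSE])
  rownames(m) <- df$accession
  m
}

#' Export a clustering as Cluster 3.0 CDT + GTR files
#'
#' Writes the clustered data table (\code{.cdt}) and gene dendrogram
#' (\code{.gtr}) understood by Java TreeView and other Cluster 3.0
#' viewers. Rows appear in dendrogram leaf order; GTR node scores are
#' 1 - merge height (a correlation-like similarity under the default
#' uncentred correlation distance).
#'
#' @param clustering a \code{ClusterResult} from [clusterProfiles()].
#' @param basePath output path without extension; \code{.cdt} and
#'   \code{.gtr} are appended.
#' @return invisibly, the two file paths.
#' @export
writeCdtGtr <- function(clustering, basePath) {
  stopifnot(inherits(clustering, "ClusterResult"))
  m <- clustering$matrix
  hc <- clustering$hclust
  n <- nrow(m)
  geneId <- sprintf("GENE%dX", seq_len(n))
  # GTR: one line per merge; negative = leaf, positive = earlier node
  ref <- function(i) if (i < 0) geneId[-i] else sprintf("NODE%dX", i)
  gtr <- vapply(seq_len(n - 1L), function(k) {
    paste(sprintf("NODE%dX", k), ref(hc$merge[k, 1L]),
          ref(hc$merge[k, 2L]),
          format(1 - hc$height[k], digits = 10), sep = "\t")
  }, character(1))
  gtrPath <- paste0(basePath, ".gtr")
  writeLines(gtr, gtrPath)
  cdtPath <- paste0(basePath, ".cdt")
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                   collapse = "\t")
  rows <- vapply(hc$order, function(i) {
    paste(c(geneId[i], rownames(m)[i], rownames(m)[i], "1",
            format(m[i, ], digits = 10)), collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, rows), cdtPath)
  invisible(c(cdt = cdtPath, gtr = gtrPath))
}

#' Write a generic results data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
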