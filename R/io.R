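#' @include AllClasses.R populations.R
NULL

#' Landscape and truth serialization (JSON)
#'
#' \code{writeLandscapeJSON}/\code{readLandscapeJSON} round-trip a
#' \code{\link{VariantLandscape}}; \code{writePlantedTruthJSON} exports a
#' panel's ground truth.
#'
#' @param landscape a \code{\link{VariantLandscape}}.
#' @param truth a \code{PlantedTruth} object.
#' @param path file path.
#' @return \code{readLandscapeJSON} returns a
#'   \code{\link{VariantLandscape}}; the writers return \code{path}
#'   invisibly.
#' @export
writeLandscapeJSON <- function(landscape, path) {
    x <- list(variant_id = landscape@variantId,
              temperature = landscape@temperature,
              basins = lapply(landscape@basins, function(b)
                  list(id = b@id, center = b@center, depth = b@depth,
                       width = b@width)),
              perturbations = as.list(landscape@perturbations))
    write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeLandscapeJSON
#' @export
readLandscapeJSON <- function(path) {
    x <- read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    basinList <- lapply(x$basins, function(b)
        Basin(b$id, unlist(b$center), b$depth, b$width))
    VariantLandscape(x$variant_id, basinList,
                     perturbations = unlist(x$perturbations),
                     temperature = x$temperature)
}

#' @rdname writeLandscapeJSON
#' @export
writePlantedTruthJSON <- function(truth, path) {
    write_json(list(designated = as.list(truth@designated),
                    threshold = truth@threshold,
                    populations = truth@populations),
               path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Phenotype matrix CSV (rows = variants, columns = targets)
#'
#' Binding calls are encoded 1 (binds), 0 (no binding) and NA
#' (undetermined).
#'
#' @param pheno a \code{\link{PhenotypeMatrix}}.
#' @param path file path.
#' @return \code{readPhenotypeMatrix} returns a
#'   \code{\link{PhenotypeMatrix}}.
#' @export
writePhenotypeMatrix <- function(pheno, path) {
    calls <- phenotypeCalls(pheno)
    num <- matrix(NA_integer_, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
    num[calls == "binds"] <- 1L
    num[calls == "no_binding"] <- 0L
    write.csv(as.data.frame(num, check.names = FALSE), path, row.names = TRUE)
    invisible(path)
}

#' @rdname writePhenotypeMatrix
#' @export
readPhenotypeMatrix <- function(path) {
    num <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    calls <- matrix("undetermined", nrow(num), ncol(num),
                    dimnames = dimnames(num))
    calls[!is.na(num) & num == 1] <- "binds"
    calls[!is.na(num) & num == 0] <- "no_binding"
    PhenotypeMatrix(calls)
}

#' Snapshot ensemble CSV (time plus one column per torsion)
#'
#' The variant id and bath temperature travel in a leading comment line.
#'
#' @param snapshots a \code{\link{SnapshotSet}}.
#' @param path file path.
#' @return \code{readSnapshotCSV} returns a \code{\link{SnapshotSet}}.
#' @export
writeSnapshotCSV <- function(snapshots, path) {
    X <- frames(snapshots)
    colnames(X) <- paste0("torsion", seq_len(ncol(X)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# variant=%s temperature=%g",
                       variantId(snapshots), bathTemperature(snapshots)), con)
    write.csv(data.frame(time = frameTimes(snapshots), X), con,
              row.names = FALSE)
    invisible(path)
}

#' @rdname writeSnapshotCSV
#' @export
readSnapshotCSV <- function(path) {
    hdr <- readLines(path, n = 1)
    variant <- sub("^# variant=(\\S+) .*$", "\\1", hdr)
    temp <- as.numeric(sub("^.* temperature=(\\S+)$", "\\1", hdr))
    df <- read.csv(path, comment.char = "#")
    new("SnapshotSet", variantId = variant, temperature = temp,
        frames = as.matrix(df[, -1, drop = FALSE]),
        times = as.numeric(df$time))
}

#' Clone library FASTA
#'
#' Writes the parent as the first record (id \code{"parent"}) followed by
#' the clones; \code{readCloneLibrary} reads any aptamer FASTA into an
#' \code{AAStringSet}.
#'
#' @param lib a \code{\link{CloneLibrary}}.
#' @param path file path.
#' @return \code{readCloneLibrary} returns an \code{AAStringSet}.
#' @export
writeCloneLibrary <- function(lib, path) {
    all <- c(AAStringSet(setNames(lib@parent, "parent")),
             cloneSequences(lib))
    writeXStringSet(all, path)
    invisible(path)
}

#' @rdname writeCloneLibrary
#' @export
readCloneLibrary <- function(path) {
    readAAStringSet(path)
}

#' Population table TSV export
#'
#' One row per (variant, conformer): population percentage, SEM, populated
#' flag and free energy; not-populated rows carry \code{"n.p."} in the
#' free-energy column. Percentages are exported rounded to one decimal;
#' full precision stays in the \code{\link{PopulationTable}} object.
#'
#' @param pop a \code{\link{PopulationTable}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePopulationTable <- function(pop, path) {
    tb <- as.data.frame(pop)
    out <- data.frame(variant = tb$variant, conformer = tb$conformer,
                      pop_pct = round(tb$pop_pct, 1),
                      sem_pct = round(tb$sem_pct, 1),
                      populated = tb$populated,
                      dG_kcal_mol = ifelse(tb$populated,
                                           sprintf("%.2f", tb$dG_kcal_mol),
                                           "n.p."))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Candidate report JSON export
#'
#' @param report a \code{\link{CandidateReport}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeCandidateReport <- function(report, path) {
    write_json(list(target = report@target, binders = report@binderSet,
                    non_binders = report@nonBinderSet,
                    considered = report@considered,
                    candidates = report@candidateSet,
                    accessibility_cost = as.list(report@cost),
                    exclusions = report@exclusionLog,
                    dG_max = if (is.na(report@dGmax)) NULL else report@dGmax,
                    no_binders = report@noBinders),
               path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
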