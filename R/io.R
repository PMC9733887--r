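# Plain-text interchange formats. Events travel as two-column TSV
# (channel_id, time_ms) for both sampling paths, so spike-sorted
# experimental data can be substituted for simulated recordings.

#' Write an event series as two-column TSV
#'
#' @param events an \linkS4class{EventSeries}.
#' @param path output file.
#' @export
writeEvents <- function(events, path) {
    stopifnot(is(events, "EventSeries"))
    write.table(eventTable(events), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read an event series from two-column TSV
#'
#' @param path file with columns channel_id, time_ms.
#' @param nChannels,duration record dimensions; defaults inferred from the
#'   data.
#' @return an \linkS4class{EventSeries}.
#' @export
readEvents <- function(path, nChannels = NULL, duration = NULL) {
    df <- read.table(path, header = TRUE, sep = "\t")
    eventSeries(df$channel_id, df$time_ms, nChannels = nChannels,
                duration = duration)
}

#' Write a spike raster as two-column TSV (time_ms, neuron_id)
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param path output file.
#' @export
writeRaster <- function(raster, path) {
    stopifnot(is(raster, "SpikeRaster"))
    write.table(data.frame(time_ms = (raster@step - 1) * raster@dt,
                           neuron_id = raster@neuron),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a coarse record as CSV (one row per channel)
#'
#' @param record a \linkS4class{CoarseRecord}.
#' @param path output file.
#' @export
writeSignalCSV <- function(record, path) {
    stopifnot(is(record, "CoarseRecord"))
    write.table(record@signal, path, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a channel x time matrix from CSV
#'
#' @param path CSV with one row per channel.
#' @param dt sampling interval, ms.
#' @return numeric matrix with attribute "dt"; pass to [extractEvents()].
#' @export
readSignalCSV <- function(path, dt) {
    m <- as.matrix(read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    structure(m, dt = dt)
}

#' Export a topology edge list as TSV (i, j, d_ij, w_ij)
#'
#' Intended for small fixtures; full-scale topologies are large.
#'
#' @param topology a \linkS4class{NetworkTopology}.
#' @param path output file.
#' @export
exportTopologyTSV <- function(topology, path) {
    stopifnot(is(topology, "NetworkTopology"))
    n <- nrow(topology@geometry@positions)
    rows <- lapply(seq_len(n), function(i) {
        tl <- targetsOf(topology, i)
        if (!nrow(tl)) return(NULL)
        data.frame(i = i, j = tl$target, d_ij = tl$distance,
                   w_ij = tl$weight)
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
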