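# HDF5 container I/O.
#
# Layout:
#   /traces/<label>   1-D float32 dataset
#                     attrs: fs, kind, units, ap_mm, ml_mm, dv_mm, state
#   /spikes/<label>   1-D float64 spike times in seconds
#   root attrs:       duration_s, schema_version

SCHEMA_VERSION <- "1.0"

#' Save a dataset to an HDF5 container
#'
#' Samples are stored as float32 (the round trip is bit-faithful at single
#' precision); spike times as float64. The `/spikes` group is written only
#' when spike trains are present.
#'
#' @param dataset a `theta_dataset`.
#' @param path output `.h5` file.
#' @param overwrite replace an existing file? Default `FALSE`.
#' @export
save_dataset <- function(dataset, path, overwrite = FALSE) {
  stopifnot(inherits(dataset, "theta_dataset"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path, " (use overwrite = TRUE)")
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "traces")
  for (tr in dataset$traces) {
    nm <- paste0("traces/", tr$label)
    rhdf5::h5createDataset(path, nm, dims = length(tr$samples),
                           storage.mode = "double", H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(tr$samples, path, nm)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, nm)
    rhdf5::h5writeAttribute(tr$fs, did, "fs")
    rhdf5::h5writeAttribute(tr$kind, did, "kind")
    rhdf5::h5writeAttribute("mV", did, "units")
    if (!is.null(tr$coords)) {
      rhdf5::h5writeAttribute(tr$coords[["ap"]], did, "ap_mm")
      rhdf5::h5writeAttribute(tr$coords[["ml"]], did, "ml_mm")
      rhdf5::h5writeAttribute(tr$coords[["dv"]], did, "dv_mm")
    }
    if (!is.null(tr$state)) rhdf5::h5writeAttribute(tr$state, did, "state")
    rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  }
  if (!is.null(dataset$spikes) && length(dataset$spikes)) {
    rhdf5::h5createGroup(path, "spikes")
    for (lb in names(dataset$spikes))
      rhdf5::h5write(dataset$spikes[[lb]]$times_s, path,
                     paste0("spikes/", lb))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(dataset$duration_s, fid, "duration_s")
  rhdf5::h5writeAttribute(SCHEMA_VERSION, fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a dataset from an HDF5 container
#'
#' Channels declaring `units = "uV"` are converted to mV on load. A channel
#' missing a required attribute (`fs` or `kind`) raises a format error
#' naming the channel.
#'
#' @param path `.h5` file written by [save_dataset()] (or following the
#'   same layout).
#' @return a `theta_dataset`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  tr_names <- contents$name[contents$group == "/traces" &
                              contents$otype == "H5I_DATASET"]
  if (!length(tr_names)) stop("container has no /traces group: ", path)
  traces <- vector("list", length(tr_names))
  for (i in seq_along(tr_names)) {
    lb <- tr_names[i]
    nm <- paste0("traces/", lb)
    x <- as.numeric(rhdf5::h5read(path, nm))
    at <- rhdf5::h5readAttributes(path, nm)
    if (is.null(at$fs))
      stop("format error: channel '", lb, "' lacks required attribute 'fs'")
    if (is.null(at$kind))
      stop("format error: channel '", lb, "' lacks required attribute 'kind'")
    coords <- NULL
    if (!is.null(at$ap_mm))
      coords <- c(as.numeric(at$ap_mm), as.numeric(at$ml_mm),
                  as.numeric(at$dv_mm))
    traces[[i]] <- theta_trace(x, fs = as.numeric(at$fs), kind = as.character(at$kind),
                         label = lb, coords = coords,
                         units = if (is.null(at$units)) "mV"
                                 else as.character(at$units),
                         state = if (is.null(at$state)) NULL
                                 else as.character(at$state))
  }
  spikes <- NULL
  sp_names <- contents$name[contents$group == "/spikes" &
                              contents$otype == "H5I_DATASET"]
  if (length(sp_names)) {
    spikes <- lapply(sp_names, function(lb)
      spike_train(as.numeric(rhdf5::h5read(path, paste0("spikes/", lb)))))
    names(spikes) <- sp_names
  }
  root <- rhdf5::h5readAttributes(path, "/")
  meta <- list()
  if (!is.null(root$schema_version))
    meta$schema_version <- as.character(root$schema_version)
  theta_dataset(traces, spikes = spikes, meta = meta)
}
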