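# Dataset serialization: 4-D NIfTI volume (x, y, z, protocol entry) with a
# CSV protocol sidecar and a JSON metadata file, plus a flat CSV mode for
# single-voxel work.

#' Write / read a synthetic IVIM dataset
#'
#' `write_ivim_dataset` stores a dataset as `<prefix>.nii.gz` (4-D volume),
#' `<prefix>_protocol.csv` (columns `b_s_mm2`, `T_ms`, `fc_flag`, plus the
#' shared timing in a comment-free extra row-wise representation via the
#' JSON metadata) and `<prefix>_meta.json` (generating parameters, seed,
#' SNR, timing). A voxels-by-entries matrix is written as an
#' `n x 1 x 1 x entries` volume. `read_ivim_dataset` reconstructs the
#' volume, the protocol (with `delta`/`Delta` attributes) and the
#' metadata, so a round trip preserves the generating parameters and seed
#' exactly.
#'
#' @param data 4-D array or voxels-by-entries matrix (e.g. from
#'   [synthetic_voxels()]).
#' @param prefix Output path prefix.
#' @param protocol Protocol data frame; defaults to the one attached to
#'   `data`.
#' @return `write_ivim_dataset` returns `prefix` invisibly;
#'   `read_ivim_dataset` returns a list `data`, `protocol`, `meta`.
#' @export
write_ivim_dataset <- function(data, prefix,
                               protocol = attr(data, "protocol")) {
  if (is.null(protocol)) .stopf("no protocol supplied or attached")
  vol <- if (is.matrix(data)) {
    array(as.numeric(data), c(nrow(data), 1, 1, ncol(data)))
  } else data
  if (dim(vol)[4] != nrow(protocol))
    .stopf("4th dimension (%d) does not match protocol rows (%d)",
           dim(vol)[4], nrow(protocol))
  RNifti::writeNifti(RNifti::asNifti(vol), paste0(prefix, ".nii.gz"))
  utils::write.csv(
    data.frame(b_s_mm2 = protocol$b, T_ms = protocol$T,
               fc_flag = as.integer(protocol$m < 0)),
    paste0(prefix, "_protocol.csv"), row.names = FALSE)
  p <- attr(data, "params")
  meta <- list(delta_ms = attr(protocol, "delta"),
               Delta_ms = attr(protocol, "Delta"),
               n_directions = attr(protocol, "n_directions"),
               snr = attr(data, "snr"),
               seed = attr(data, "seed"),
               was_matrix = is.matrix(data),
               params = if (!is.null(p)) unclass(p))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_ivim_dataset
#' @export
read_ivim_dataset <- function(prefix) {
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  tab <- utils::read.csv(paste0(prefix, "_protocol.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  pro <- data.frame(b = tab$b_s_mm2, T = tab$T_ms,
                    m = ifelse(tab$fc_flag > 0, -1, 1))
  attr(pro, "delta") <- meta$delta_ms
  attr(pro, "Delta") <- meta$Delta_ms
  attr(pro, "n_directions") <- meta$n_directions
  class(pro) <- c("acquisition_protocol", "data.frame")
  data <- array(as.numeric(vol), dim(vol))
  if (isTRUE(meta$was_matrix))
    data <- matrix(data, dim(vol)[1], dim(vol)[4])
  params <- if (!is.null(meta$params))
    do.call(ivim_params, meta$params[c("f", "D", "v", "tau", "S0", "Db",
                                       "d")])
  attr(data, "protocol") <- pro
  attr(data, "params") <- params
  attr(data, "snr") <- meta$snr
  attr(data, "seed") <- meta$seed
  list(data = data, protocol = pro, meta = meta)
}
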