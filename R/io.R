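# Plain-text I/O for the pipeline's artifacts: ligand tables as CSV,
# binding sites as JSON, sensorgrams as CSV with a JSON sidecar.

#' Read / write a ligand table
#'
#' CSV with header `id, name, mass, solubility, bbb_penetration,
#' plasma_conc, ad_refs, is_fatty_acid` (mass in Da, solubility in uM, BBB
#' in percent, plasma concentration in nM).
#'
#' @param records Ligand table `data.frame`.
#' @param path File path.
#' @return `write_ligand_table()`: `path`, invisibly;
#'   `read_ligand_table()`: the table.
#' @export
write_ligand_table <- function(records, path) {
  validate_ligand_table(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ligand_table
#' @export
read_ligand_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$is_fatty_acid <- as.logical(tab$is_fatty_acid)
  validate_ligand_table(tab)
  tab
}

#' Read / write binding-site collections as JSON
#'
#' Each site is an object `{ligand_id, residues: [{number, aa}, ...],
#' true_cluster}` (the hidden generator label is optional and ignored by
#' the clustering).
#'
#' @param sites List of [binding_site()] objects.
#' @param path File path.
#' @return `write_binding_sites()`: `path`, invisibly;
#'   `read_binding_sites()`: list of [binding_site()] objects.
#' @export
write_binding_sites <- function(sites, path) {
  payload <- lapply(sites, function(s) {
    out <- list(ligand_id = s$ligand_id,
                residues = s$residues)
    if (!is.null(s$true_cluster)) out$true_cluster <- s$true_cluster
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binding_sites
#' @export
read_binding_sites <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    res <- payload$residues[[i]]
    binding_site(payload$ligand_id[i], res$number, res$aa,
                 true_cluster = if ("true_cluster" %in% names(payload))
                   payload$true_cluster[i])
  })
}

#' Read / write a sensorgram as CSV plus JSON sidecar
#'
#' The CSV holds columns `time_s` and `response_RU`; the sidecar
#' (`<path>.json`) records the analyte concentration (M) and phase
#' boundary (s).
#'
#' @param sg A [sensorgram()].
#' @param path CSV file path.
#' @return `write_sensorgram()`: `path`, invisibly; `read_sensorgram()`:
#'   a [sensorgram()].
#' @export
write_sensorgram <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  write.csv(data.frame(time_s = sg$time, response_RU = sg$response),
            path, row.names = FALSE)
  meta <- list(conc_M = attr(sg, "conc"), t_assoc_s = attr(sg, "t_assoc"))
  if (!is.null(attr(sg, "noise_sd"))) meta$noise_sd <- attr(sg, "noise_sd")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  tab <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sensorgram(tab$time_s, tab$response_RU, meta$conc_M, meta$t_assoc_s)
}
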