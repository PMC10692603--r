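#' Read and write 8-bit multi-page TIFF stacks
#'
#' Stacks are integer arrays (y pixels, x pixels, frames) with values in
#' [0, 255]. Writing and re-reading is lossless. Higher-bit-depth input
#' is accepted with a warning and linearly rescaled to 8-bit.
#'
#' @param stack integer array (y, x, frames), values in [0, 255].
#' @param path file path.
#' @return `read_stack`: an integer array (y, x, frames).
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  if (any(stack < 0 | stack > 255)) stop("stack is not 8-bit")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) stack[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mx <- max(vapply(pages, max, 0))
  if (mx > 255) {
    warning("input is not 8-bit; linearly rescaling to [0, 255]")
    pages <- lapply(pages, function(p) round(p * 255 / 65535))
  }
  array(as.integer(unlist(pages)),
        dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
}

#' CSV tables with a provenance header
#'
#' All pipeline tables are comma-separated, UTF-8, '.' decimal, with a
#' header row, preceded by '#'-prefixed provenance comment lines
#' (package version, configuration hash, seed). `read_table` checks that
#' required columns are present and names any that are missing.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param provenance character vector of provenance lines (without the
#'   leading '#').
#' @return `read_table`: a data.frame.
#' @export
write_table <- function(df, path, provenance = character()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param required_cols character vector of columns that must exist.
#' @export
read_table <- function(path, required_cols = NULL) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

# deterministic 31-bit polynomial hash of a string, for provenance
config_hash <- function(x) {
  if (!is.character(x)) x <- yaml::as.yaml(x)
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read species rules from a YAML block or file
#'
#' Expected structure: a list of mappings with keys `species`,
#' optional `radius_min`, `radius_max` (um) and `max_linking_distance`
#' (um).
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return a [species_rules()] object.
#' @export
read_species_rules <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  df <- do.call(rbind, lapply(x, function(r) data.frame(
    species = r$species,
    radius_min = r$radius_min %||% NA_real_,
    radius_max = r$radius_max %||% NA_real_,
    max_linking_distance = r$max_linking_distance,
    stringsAsFactors = FALSE)))
  species_rules(df)
}

#' Read microenvironment definitions from YAML
#'
#' Expected structure: list of mappings with keys `name`, `species`,
#' `cells` (list of grid labels) and `frames` (two-element inclusive
#' range).
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return named list of [microenvironment()]s.
#' @export
read_microenvironments <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  envs <- lapply(x, function(e)
    microenvironment(e$name, unlist(e$cells), unlist(e$frames),
                     e$species))
  names(envs) <- vapply(envs, `[[`, "", "name")
  envs
}
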