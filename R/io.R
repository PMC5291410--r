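# Readers and writers for the on-disk formats: tidy profile/expression TSVs,
# the circuit parameter file, and run manifests.

#' Read profile or expression tables
#'
#' Reads a TSV with columns `time_min` (or `time_class`), `position_pct`,
#' `species`, `concentration` into either a tidy data frame or, when the
#' table forms a complete grid, an `external_profiles` object.
#'
#' @param path file path.
#' @param as `"table"` (tidy data frame) or `"profiles"`.
#' @param species allowed species names; others are rejected.
#' @param schedule optional `stage_schedule` for resolving `time_class`
#'   labels.
#' @return data frame or `external_profiles`.
#' @export
read_profiles <- function(path, as = c("table", "profiles"),
                          species = NULL, schedule = NULL) {
  as <- match.arg(as)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df)) {
    if (!"time_class" %in% names(df))
      stop("missing column time_min (or time_class) in ", path)
    if (is.null(schedule)) schedule <- stage_schedule()
    df$time_min <- resolve_time(df$time_class, schedule)
    df$time_class <- NULL
  }
  need <- c("time_min", "position_pct", "species", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  bad <- which(!is.finite(df$concentration) | df$concentration < 0)
  if (length(bad) > 0)
    stop("negative or non-finite concentration at data line ", bad[1],
         " of ", path)
  if (!is.null(species)) {
    unknown <- setdiff(unique(df$species), species)
    if (length(unknown) > 0)
      stop("unknown species in ", path, ": ",
           paste(unknown, collapse = ", "))
  }
  key <- paste(df$time_min, df$position_pct, df$species)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (time, position, species) key at data line ", dup,
         " of ", path)
  }
  df <- df[order(df$species, df$time_min, df$position_pct), need]
  rownames(df) <- NULL
  if (as == "table") return(df)
  times <- sort(unique(df$time_min))
  positions <- sort(unique(df$position_pct))
  sp <- sort(unique(df$species))
  vals <- array(NA_real_, c(length(times), length(positions), length(sp)))
  ti <- match(df$time_min, times)
  pi <- match(df$position_pct, positions)
  si <- match(df$species, sp)
  vals[cbind(ti, pi, si)] <- df$concentration
  if (any(is.na(vals)))
    stop("profile table in ", path, " is not a complete grid")
  external_profiles(times, positions, vals, sp)
}

#' Write a tidy table or profiles to TSV
#'
#' Deterministic output: stable row ordering and fixed 6-significant-digit
#' float formatting.
#'
#' @param x data frame with the tidy columns, or an `external_profiles`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  if (inherits(x, "external_profiles")) x <- as.data.frame(x)
  x <- x[order(x$species, x$time_min, x$position_pct), , drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write circuit parameters to a structured text file
#'
#' Key/value sections for the vectors and row-per-target matrix sections for
#' `W`, `E`, and the optional sign mask, with a header naming the regulator
#' order.
#'
#' @param params a `circuit_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  fmt <- function(v) paste(signif(v, 8), collapse = " ")
  lines <- c(
    "# gapdyn circuit parameter file",
    paste("gene_names:", paste(params$gene_names, collapse = " ")),
    paste("external_names:", paste(params$external_names, collapse = " ")),
    paste("R:", fmt(params$R)),
    paste("D:", fmt(params$D_base)),
    paste("lambda:", fmt(params$lambda)),
    paste("h:", fmt(params$h)),
    paste0("W:  # rows = target, columns = ",
           paste(params$gene_names, collapse = " ")))
  for (a in seq_along(params$gene_names))
    lines <- c(lines, paste0(params$gene_names[a], ": ", fmt(params$W[a, ])))
  lines <- c(lines, paste0("E:  # rows = target, columns = ",
                           paste(params$external_names, collapse = " ")))
  for (a in seq_along(params$gene_names))
    lines <- c(lines, paste0(params$gene_names[a], ": ", fmt(params$E[a, ])))
  if (!is.null(params$sign_mask)) {
    for (nm in c("W", "E")) {
      if (is.null(params$sign_mask[[nm]])) next
      lines <- c(lines, paste0("sign_", nm, ":"))
      for (a in seq_along(params$gene_names))
        lines <- c(lines, paste0(params$gene_names[a], ": ",
                                 paste(params$sign_mask[[nm]][a, ],
                                       collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a circuit parameter file
#'
#' @param path file written by [write_parameters()] (or hand-edited in the
#'   same dialect). The external-regulator column order in the `E` header
#'   may be any permutation of the declared `external_names`; columns are
#'   re-ordered to match.
#' @return a validated `circuit_parameters` object.
#' @export
read_parameters <- function(path) {
  raw <- readLines(path)
  strip <- function(s) sub("\\s*#.*$", "", s)
  raw <- trimws(vapply(raw, strip, character(1), USE.NAMES = FALSE))
  raw <- raw[nzchar(raw)]
  kv <- list()
  i <- 1L
  get_scalar_lines <- function() {
    out <- list()
    while (i <= length(raw)) {
      line <- raw[i]
      key <- sub(":.*$", "", line)
      val <- trimws(sub("^[^:]*:", "", line))
      out[[key]] <- val
      i <<- i + 1L
      if (key %in% c("W", "E", "sign_W", "sign_E")) {
        # matrix section: following lines are rows keyed by gene name
        rows <- character(0)
        while (i <= length(raw) &&
               sub(":.*$", "", raw[i]) %in% strsplit(out$gene_names, " +")[[1]]) {
          rows <- c(rows, trimws(sub("^[^:]*:", "", raw[i])))
          i <<- i + 1L
        }
        out[[key]] <- rows
      }
    }
    out
  }
  kv <- get_scalar_lines()
  genes <- strsplit(kv$gene_names, " +")[[1]]
  ext <- strsplit(kv$external_names, " +")[[1]]
  nums <- function(s) as.numeric(strsplit(s, " +")[[1]])
  mat <- function(rows, ncol) {
    m <- do.call(rbind, lapply(rows, nums))
    if (ncol(m) != ncol) stop("matrix row length mismatch in ", path)
    m
  }
  W <- mat(kv$W, length(genes))
  E <- mat(kv$E, length(ext))
  # header of the E section may permute regulator order
  ehdr <- grep("^E:", readLines(path), value = TRUE)[1]
  if (grepl("columns =", ehdr)) {
    order_in_file <- strsplit(trimws(sub(".*columns =", "", ehdr)), " +")[[1]]
    if (setequal(order_in_file, ext) && !identical(order_in_file, ext))
      E <- E[, match(ext, order_in_file), drop = FALSE]
  }
  sign_mask <- NULL
  if (!is.null(kv$sign_W) || !is.null(kv$sign_E)) {
    sign_mask <- list(
      W = if (!is.null(kv$sign_W)) mat(kv$sign_W, length(genes)) else NULL,
      E = if (!is.null(kv$sign_E)) mat(kv$sign_E, length(ext)) else NULL)
  }
  circuit_parameters(R = nums(kv$R), lambda = nums(kv$lambda), W = W, E = E,
                     h = nums(kv$h), D_base = nums(kv$D),
                     gene_names = genes, external_names = ext,
                     sign_mask = sign_mask)
}

#' Write a run manifest
#'
#' JSON record of a pipeline stage: command, seeds, parameter hash, inputs
#' and outputs, so each output directory is regenerable.
#'
#' @param path output path (JSON).
#' @param command stage name.
#' @param seed RNG seed(s) used.
#' @param params optional `circuit_parameters` (hashed into the record).
#' @param inputs,outputs character vectors of file paths.
#' @param extra named list merged into the record.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA_integer_, params = NULL,
                           inputs = character(0), outputs = character(0),
                           extra = list()) {
  manifest <- c(list(command = command, seed = seed,
                     parameter_hash = if (is.null(params)) NA_character_
                     else params_hash(params),
                     inputs = inputs, outputs = outputs,
                     tool = paste0("gapdyn ",
                                   as.character(utils::packageVersion("gapdyn"))),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

params_hash <- function(params) {
  v <- c(params$R, params$D_base, params$lambda, as.vector(params$W),
         as.vector(params$E), params$h)
  # order-sensitive polynomial hash; stable across platforms
  x <- sum(signif(v, 10) * seq_along(v)^1.5)
  sprintf("%.10e", x)
}
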