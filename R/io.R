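#' Read landmark configurations from a TPS file
#'
#' Minimal TPS support: `LM=`/`LM3=` blocks of coordinates, `ID=` specimen
#' identifiers (falling back to `IMAGE=` then a running index), and per-block
#' `SCALE=` factors applied multiplicatively to the coordinates. All
#' configurations must share landmark count and dimensionality.
#'
#' @param path TPS file.
#' @param species optional species label per specimen (recycled); defaults
#'   to `"sp1"`.
#' @return a specimen table (see [sample_specimens()]).
#' @export
read_tps <- function(path, species = "sp1") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM= blocks found in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1, length(lines))
  specs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (b in seq_along(starts)) {
    header <- lines[starts[b]]
    d <- if (startsWith(header, "LM3=")) 3L else 2L
    L <- as.integer(sub("^LM3?=", "", header))
    block <- lines[(starts[b] + 1):ends[b]]
    coord_lines <- grep("^[-0-9.+eE ]+$", block, value = TRUE)[seq_len(L)]
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), as.numeric))
    if (ncol(xy) != d || nrow(xy) != L) {
      stop("malformed TPS block ", b, call. = FALSE)
    }
    sc <- grep("^SCALE=", block, value = TRUE)
    if (length(sc)) xy <- xy * as.numeric(sub("^SCALE=", "", sc[1]))
    id <- grep("^ID=", block, value = TRUE)
    img <- grep("^IMAGE=", block, value = TRUE)
    ids[b] <- if (length(id)) sub("^ID=", "", id[1]) else
      if (length(img)) sub("^IMAGE=", "", img[1]) else paste0("spec", b)
    specs[[b]] <- xy
  }
  dims <- vapply(specs, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("all TPS configurations must share landmark count and dimension",
         call. = FALSE)
  }
  L <- dims[1, 1]; d <- dims[2, 1]
  flat <- t(vapply(specs, function(m) as.vector(t(m)), numeric(L * d)))
  colnames(flat) <- landmark_labels(L, d)
  data.frame(specimen = ids, species = rep_len(species, length(ids)), flat,
             check.names = FALSE)
}

#' Write landmark configurations to a TPS file
#'
#' @param tab specimen table with `lm<i>_<axis>` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(tab, path) {
  parts <- specimens_to_array(tab)
  n <- dim(parts$coords)[1]; L <- dim(parts$coords)[2]; D <- dim(parts$coords)[3]
  tag <- if (D == 3) "LM3=" else "LM="
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(paste0(tag, L), con)
    m <- matrix(parts$coords[i, , ], L, D)
    writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
               con)
    writeLines(paste0("ID=", parts$specimen[i]), con)
  }
  invisible(path)
}

#' Write / read a labelled trait matrix as CSV
#'
#' The matrix kind (covariance/correlation) is stored in the name of the
#' first column so a round trip preserves it.
#'
#' @param M a `trait_matrix`.
#' @param path CSV path.
#' @return `path` invisibly / a `trait_matrix`.
#' @export
write_trait_matrix <- function(M, path) {
  df <- data.frame(trait = rownames(M), unclass(M), check.names = FALSE)
  names(df)[1] <- paste0("trait.", tm_kind(M))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  kind <- sub("^trait\\.", "", names(df)[1])
  if (!kind %in% c("covariance", "correlation")) kind <- "covariance"
  labels <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  M <- (M + t(M)) / 2
  trait_matrix(M, kind = kind, labels = labels)
}

#' Write a character matrix to NEXUS
#'
#' Standard-datatype NEXUS via [ape::write.nexus.data()], for downstream
#' phylogenetics tools.
#'
#' @param chars a `character_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_characters_nexus <- function(chars, path) {
  rows <- split(unclass(chars), row(chars))
  dat <- lapply(seq_len(nrow(chars)), function(i) as.character(chars[i, ]))
  names(dat) <- rownames(chars)
  ape::write.nexus.data(dat, path, format = "standard", interleaved = FALSE)
  invisible(path)
}
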