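# File I/O for labeled clouds: an extended PLY dialect and a TSV table.
#
# PLY vertex properties, in order:
#   x y z nx ny nz r01 g01 b01 ... r15 g15 b15 semantic instance
# Positions/normals/colors are stored as float64 ("double") so round trips
# are lossless; `semantic` is a uchar code and `instance` an int code:
#   semantic: 0=SOIL_BASE 1=STICK 2=STEMWORK 3=OTHER_BIO 4=UNCLASSIFIED
#   instance: -3=SOIL_BASE -2=STICK -1=STEM 0=UNCLASSIFIED k>=1 = LEAF_k
# Metadata travels in `comment key=value` header lines.

SEMANTIC_CODES <- stats::setNames(0:4, SEMANTIC_CLASSES)

instance_to_code <- function(instance) {
  code <- integer(length(instance))
  code[instance == "SOIL_BASE"] <- -3L
  code[instance == "STICK"] <- -2L
  code[instance == "STEM"] <- -1L
  code[instance == "UNCLASSIFIED"] <- 0L
  isleaf <- grepl("^LEAF_[0-9]+$", instance)
  code[isleaf] <- as.integer(sub("^LEAF_", "", instance[isleaf]))
  code
}

code_to_instance <- function(code) {
  out <- character(length(code))
  out[code == -3L] <- "SOIL_BASE"
  out[code == -2L] <- "STICK"
  out[code == -1L] <- "STEM"
  out[code == 0L] <- "UNCLASSIFIED"
  pos <- code > 0L
  out[pos] <- paste0("LEAF_", code[pos])
  if (any(code < -3L)) stop("unknown instance code: ", min(code))
  out
}

cloud_field_names <- function() {
  c("x", "y", "z", "nx", "ny", "nz", color_channel_names(),
    "semantic", "instance")
}

meta_comment_lines <- function(meta) {
  c(sprintf("comment plant_id=%s", meta$plant_id),
    sprintf("comment cultivar=%s", meta$cultivar),
    sprintf("comment normalized=%d", as.integer(isTRUE(meta$normalized))),
    if (is.finite(meta$height_scale))
      sprintf("comment height_scale=%.10g", meta$height_scale),
    if (all(is.finite(meta$xy_offset)))
      sprintf("comment xy_offset=%.10g,%.10g", meta$xy_offset[1],
              meta$xy_offset[2]),
    if (is.finite(meta$z_offset %||% NA_real_))
      sprintf("comment z_offset=%.10g", meta$z_offset))
}

parse_meta_comments <- function(comments) {
  meta <- list()
  kv <- regmatches(comments, regexec("^([a-z_]+)=(.*)$", comments))
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[2]; val <- m[3]
    meta[[key]] <- switch(key,
      plant_id = , cultivar = val,
      normalized = as.integer(val) == 1L,
      height_scale = , z_offset = as.numeric(val),
      xy_offset = as.numeric(strsplit(val, ",")[[1]]),
      val)
  }
  meta
}

cloud_to_table <- function(cloud) {
  df <- data.table::as.data.table(
    cbind(cloud$positions, cloud$normals, cloud$colors))
  df[, `:=`(semantic = SEMANTIC_CODES[as.character(cloud$semantic)],
            instance = instance_to_code(cloud$instance))]
  data.table::setnames(df, cloud_field_names())
  df
}

table_to_cloud <- function(df, meta) {
  need <- cloud_field_names()
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing required property: ", paste(missing, collapse = ", "))
  }
  sem_code <- as.integer(df[["semantic"]])
  if (any(sem_code < 0L | sem_code > 4L)) {
    stop("unknown semantic code: ",
         sem_code[which(sem_code < 0L | sem_code > 4L)[1]])
  }
  plant_cloud(as.matrix(df[, c("x", "y", "z")]),
              as.matrix(df[, c("nx", "ny", "nz")]),
              as.matrix(df[, color_channel_names(), with = FALSE]),
              SEMANTIC_CLASSES[sem_code + 1L],
              code_to_instance(as.integer(df[["instance"]])),
              meta)
}

#' Write a labeled cloud to disk
#'
#' @param cloud a `plant_cloud`.
#' @param path output file path.
#' @param format `"ply"` (extended PLY with normals, 45 color channels and
#'   both label sets), `"tsv"` (one header line, one row per point, metadata
#'   in leading `#key=value` lines), or `"auto"` (from the file extension).
#' @param binary for PLY: write `binary_little_endian` instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "tsv"),
                        binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "ply"
  }
  validate_cloud(cloud)
  if (format == "tsv") write_cloud_tsv(cloud, path) else {
    write_cloud_ply(cloud, path, binary)
  }
  invisible(path)
}

#' Read a labeled cloud from disk
#'
#' @param path input file path (extended PLY or TSV, see [write_cloud()]).
#' @param format `"ply"`, `"tsv"` or `"auto"`.
#' @return a `plant_cloud`.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "ply"
  }
  if (format == "tsv") read_cloud_tsv(path) else read_cloud_ply(path)
}

write_cloud_tsv <- function(cloud, path) {
  meta_lines <- sub("^comment ", "#", meta_comment_lines(cloud$meta))
  df <- cloud_to_table(cloud)
  num <- formatC(as.matrix(df[, 1:51]), format = "g", digits = 12)
  body <- do.call(paste, c(lapply(seq_len(51), function(j) num[, j]),
                           list(df[["semantic"]], df[["instance"]]),
                           sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines, con)
  writeLines(paste(cloud_field_names(), collapse = "\t"), con)
  writeLines(body, con)
}

read_cloud_tsv <- function(path) {
  head_lines <- readLines(path, n = 50L)
  if (!length(head_lines)) stop("schema error: empty file")
  meta <- parse_meta_comments(sub("^#", "", grep("^#", head_lines,
                                                 value = TRUE)))
  df <- data.table::fread(path, sep = "\t", header = TRUE, skip = "x\t")
  if (!nrow(df)) stop("schema error: no points in ", path)
  table_to_cloud(df, meta)
}

write_cloud_ply <- function(cloud, path, binary = FALSE) {
  df <- cloud_to_table(cloud)
  n <- nrow(df)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  props <- cloud_field_names()
  types <- c(rep("double", 51L), "uchar", "int")
  header <- c("ply",
              sprintf("format %s 1.0", fmt),
              "comment plantaug extended labeled point cloud",
              meta_comment_lines(cloud$meta),
              sprintf("element vertex %d", n),
              sprintf("property %s %s", types, props),
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    m <- as.matrix(df)  # doubles; codes written as double then int below
    # interleave per-vertex: 51 doubles, 1 uchar, 1 int
    for (chunk in split(seq_len(n), ceiling(seq_len(n) / 20000))) {
      raw_list <- lapply(chunk, function(i) {
        c(writeBin(as.numeric(m[i, 1:51]), raw(), size = 8,
                   endian = "little"),
          writeBin(as.integer(m[i, 52]), raw(), size = 1,
                   endian = "little"),
          writeBin(as.integer(m[i, 53]), raw(), size = 4,
                   endian = "little"))
      })
      writeBin(unlist(raw_list), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    num <- formatC(as.matrix(df[, 1:51]), format = "g", digits = 12)
    body <- do.call(paste, c(lapply(seq_len(51), function(j)
      num[, j]), list(df[["semantic"]], df[["instance"]])))
    writeLines(body, con)
  }
}

read_cloud_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("schema error: no end_header in ", path)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000L) stop("schema error: header too long")
  }
  if (header[1] != "ply") stop("schema error: not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line[1])
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)[1]))
  if (is.na(n)) stop("schema error: missing 'element vertex' in ", path)
  prop_lines <- grep("^property ", header, value = TRUE)
  toks <- strsplit(prop_lines, " ")
  types <- vapply(toks, `[`, "", 2L)
  props <- vapply(toks, `[`, "", 3L)
  missing <- setdiff(cloud_field_names(), props)
  if (length(missing)) {
    stop("missing required property: ", paste(missing, collapse = ", "))
  }
  meta <- parse_meta_comments(
    sub("^comment ", "", grep("^comment [a-z_]+=", header, value = TRUE)))
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (binary) {
    sz <- sizes[types]
    if (anyNA(sz)) stop("unsupported PLY property type")
    stride <- sum(sz)
    raw_all <- readBin(con, raw(), n = n * stride)
    if (length(raw_all) < n * stride) stop("schema error: truncated PLY body")
    offs <- cumsum(c(0L, sz[-length(sz)]))
    vals <- matrix(0, n, length(props))
    vert_off <- (seq_len(n) - 1L) * stride
    for (j in seq_along(props)) {
      byte_idx <- rep(vert_off, each = sz[j]) + offs[j] +
        seq_len(sz[j])
      bytes <- raw_all[byte_idx]
      vals[, j] <- switch(types[j],
        double = , float64 = readBin(bytes, numeric(), n = n, size = 8,
                                     endian = "little"),
        float = , float32 = readBin(bytes, numeric(), n = n, size = 4,
                                    endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, integer(), n = n,
                                             size = 1, signed = FALSE,
                                             endian = "little")),
        char = , int8 = as.numeric(readBin(bytes, integer(), n = n,
                                           size = 1, signed = TRUE,
                                           endian = "little")),
        as.numeric(readBin(bytes, integer(), n = n, size = sz[j],
                           endian = "little")))
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(body)]
    if (length(body) < n) stop("schema error: truncated PLY body")
    vals <- matrix(scan(text = body[seq_len(n)], quiet = TRUE),
                   nrow = n, byrow = TRUE)
    if (ncol(vals) != length(props)) {
      stop("schema error: row width does not match property count")
    }
  }
  df <- data.table::as.data.table(vals)
  data.table::setnames(df, props)
  table_to_cloud(df, meta)
}
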