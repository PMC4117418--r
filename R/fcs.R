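## Minimal reader for Flow Cytometry Standard files, versions 2.0/3.0/3.1.
## List-mode data only; data types F (32-bit float), D (64-bit double) and
## I (unsigned integers of $PnB bits, 8/16/32/64). Returns the event matrix
## and marker names ($PnS, falling back to $PnN).

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  size <- file.size(path)

  header <- readBin(con, "raw", n = 58L)
  if (length(header) < 58L)
    stop("FCS parse error in HEADER segment: file truncated (", path, ")")
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("FCS parse error in HEADER segment: unsupported version '",
         version, "'")
  off <- function(i) {
    s <- rawToChar(header[(10 + 8 * (i - 1) + 1):(10 + 8 * i)])
    s <- gsub("[^0-9]", "", s)
    if (!nzchar(s)) NA_real_ else as.numeric(s)
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start ||
      text_end >= size)
    stop("FCS parse error in HEADER segment: invalid TEXT offsets")

  seek(con, text_start)
  text_raw <- readBin(con, "raw", n = text_end - text_start + 1L)
  if (length(text_raw) < text_end - text_start + 1L)
    stop("FCS parse error in TEXT segment: file truncated")
  delim <- rawToChar(text_raw[1L])
  fields <- strsplit(rawToChar(text_raw[-1L]), delim, fixed = TRUE)[[1]]
  if (length(fields) < 2L)
    stop("FCS parse error in TEXT segment: no keyword/value pairs")
  if (length(fields) %% 2L == 1L)
    fields <- fields[-length(fields)]
  kw <- stats::setNames(fields[seq(2L, length(fields), 2L)],
                        toupper(trimws(fields[seq(1L, length(fields), 2L)])))
  get_kw <- function(name, default = NA_character_) {
    if (name %in% names(kw)) kw[[name]] else default
  }

  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  if (is.na(n_par) || is.na(n_tot))
    stop("FCS parse error in TEXT segment: missing $PAR or $TOT")
  datatype <- toupper(get_kw("$DATATYPE", "F"))
  mode <- toupper(get_kw("$MODE", "L"))
  if (mode != "L")
    stop("FCS parse error in TEXT segment: only list mode ($MODE L) supported")
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (grepl("^1", byteord)) "little" else "big"

  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(get_kw("$BEGINDATA"))
    data_end <- as.numeric(get_kw("$ENDDATA"))
  }
  if (is.na(data_start) || is.na(data_end) || data_end < data_start ||
      data_end >= size + 1)
    stop("FCS parse error in DATA segment: invalid offsets")

  bits <- vapply(seq_len(n_par), function(i)
    as.integer(get_kw(sprintf("$P%dB", i), "32")), integer(1))
  seek(con, data_start)
  n_values <- n_par * n_tot
  values <- switch(datatype,
    "F" = readBin(con, "double", n = n_values, size = 4L, endian = endian),
    "D" = readBin(con, "double", n = n_values, size = 8L, endian = endian),
    "I" = {
      if (length(unique(bits)) != 1L || !unique(bits) %in% c(8L, 16L, 32L))
        stop("FCS parse error in DATA segment: unsupported $PnB for type I")
      readBin(con, "integer", n = n_values, size = unique(bits) / 8L,
              endian = endian, signed = unique(bits) > 16L)
    },
    stop("FCS parse error in TEXT segment: unsupported $DATATYPE '",
         datatype, "'"))
  if (length(values) < n_values)
    stop("FCS parse error in DATA segment: expected ", n_values,
         " values, read ", length(values))
  data <- matrix(as.double(values), nrow = n_tot, ncol = n_par, byrow = TRUE)

  markers <- vapply(seq_len(n_par), function(i) {
    s <- get_kw(sprintf("$P%dS", i))
    if (!is.na(s) && nzchar(trimws(s))) trimws(s)
    else {
      nm <- get_kw(sprintf("$P%dN", i))
      if (is.na(nm) || !nzchar(trimws(nm))) sprintf("P%d", i) else trimws(nm)
    }
  }, character(1))
  if (anyDuplicated(markers))
    stop("duplicate marker names in FCS file: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  list(data = data, markers = markers, keywords = kw, version = version)
}
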