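#' Channel layouts for supported isobaric plexes
#'
#' Reporter-ion m/z values for the bundled plex presets. A plex preset defines
#' the channel labels and the monoisotopic reporter m/z at which reporter ions
#' are extracted from MS2 spectra. Isotope-impurity values are lot-specific and
#' are *not* part of a preset: load them from the manufacturer's certificate
#' with [load_correction_matrix()].
#'
#' @param plex Plex name, one of `"itraq4"`, `"itraq8"`, `"tmt6"`, `"tmt8"`,
#'   `"tmt10"` (case-insensitive; `"-"`/`"_"` ignored).
#' @return A tibble with columns `label` (channel label, e.g. `"126"`) and
#'   `reporter_mz` (Th), in plex order.
#' @examples
#' plex_channels("tmt6")
#' @export
plex_channels <- function(plex) {
  key <- normalize_plex_name(plex)
  layout <- .plex_layouts[[key]]
  if (is.null(layout)) {
    stop("Unknown plex '", plex, "'. Available presets: ",
         paste(names(.plex_layouts), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(label = names(layout), reporter_mz = unname(layout))
}

#' @rdname plex_channels
#' @export
plex_presets <- function() names(.plex_layouts)

normalize_plex_name <- function(plex) {
  stopifnot(is.character(plex), length(plex) == 1L)
  tolower(gsub("[-_ ]", "", plex))
}

# Monoisotopic reporter masses (singly protonated reporter fragments).
.plex_layouts <- list(
  itraq4 = c(
    "114" = 114.11123, "115" = 115.10826, "116" = 116.11162, "117" = 117.11497
  ),
  itraq8 = c(
    "113" = 113.10787, "114" = 114.11123, "115" = 115.10826, "116" = 116.11162,
    "117" = 117.11497, "118" = 118.11201, "119" = 119.11536, "121" = 121.12206
  ),
  tmt6 = c(
    "126" = 126.127726, "127" = 127.124761, "128" = 128.134436,
    "129" = 129.131471, "130" = 130.141145, "131" = 131.138180
  ),
  tmt8 = c(
    "126" = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
    "128C" = 128.134436, "129N" = 129.131471, "130C" = 130.141145,
    "131" = 131.138180, "131C" = 131.144500
  ),
  tmt10 = c(
    "126" = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
    "128N" = 128.128116, "128C" = 128.134436, "129N" = 129.131471,
    "129C" = 129.137790, "130N" = 130.134825, "130C" = 130.141145,
    "131" = 131.138180
  )
)

#' Parse a channel-pair string
#'
#' Channel pairs are written `"num/den"`, e.g. `"127/126"`: the first label is
#' the numerator channel of the ratio, the second the denominator.
#'
#' @param pairs Character vector of pair strings.
#' @param channels Tibble from [plex_channels()] (or any tibble with a `label`
#'   column) used to validate the labels.
#' @return A tibble with columns `pair`, `numerator`, `denominator`.
#' @export
parse_channel_pairs <- function(pairs, channels = NULL) {
  stopifnot(is.character(pairs), length(pairs) >= 1L)
  parts <- strsplit(pairs, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("Malformed channel pair(s): ", paste(pairs[bad], collapse = ", "),
         " (expected 'numerator/denominator')", call. = FALSE)
  }
  out <- tibble::tibble(
    pair = pairs,
    numerator = vapply(parts, `[`, "", 1L),
    denominator = vapply(parts, `[`, "", 2L)
  )
  if (any(out$numerator == out$denominator)) {
    stop("Channel pair numerator and denominator must differ", call. = FALSE)
  }
  if (!is.null(channels)) {
    known <- channels$label
    unknown <- setdiff(c(out$numerator, out$denominator), known)
    if (length(unknown) > 0L) {
      stop("Channel label(s) not in plex: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  out
}
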