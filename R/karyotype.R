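#' Cytogenetic event vocabulary
#'
#' The 17 coded chromosomal-event categories used as binary features, covering
#' the recurrent abnormalities of myeloid neoplasms. Whole-arm losses and the
#' corresponding partial deletions are pooled (e.g. monosomy 7 and del(7q) are
#' both `"-7/7q-"`), while two categories with distinct clinical behaviour are
#' kept apart: the unbalanced derivative (1;7) translocation — which produces
#' both 1q gain and 7q loss but carries a better outcome than -7/7q- — is its
#' own code, and del(5q) is split into `"isolated_del5q"` (sole abnormality)
#' versus `"-5/5q-nonisolated"`. `"complex"` flags a karyotype with three or
#' more distinct clonal abnormalities.
#'
#' @return character vector of event codes.
#' @export
cyto_vocabulary <- function() {
  c("+8", "-20/20q-", "-7/7q-", "+1/1q+", "-5/5q-nonisolated",
    "isolated_del5q", "-17/17p-/t17", "-9/9q-", "-13/13q-", "-18",
    "-12/12p-", "-Y", "der(1;7)", "+9", "+21", "-16/16q-", "complex")
}

# map one abnormal ISCN token to a vocabulary code (or NA if unrecognised);
# del(5q) is mapped later once the whole karyotype is known (isolated or not)
.map_cyto_token <- function(tok) {
  if (tok %in% cyto_vocabulary()) return(tok)        # already coded: identity
  if (grepl("^der\\(1;7\\)", tok)) return("der(1;7)")
  if (grepl("^\\+8$", tok)) return("+8")
  if (grepl("^\\+9$", tok)) return("+9")
  if (grepl("^\\+21$", tok)) return("+21")
  if (tok == "+1" || grepl("^dup\\(1\\)\\(q", tok) || tok == "dup(1q)" ||
      grepl("^\\+1q", tok)) return("+1/1q+")
  if (tok == "-Y") return("-Y")
  if (tok == "-5") return("-5/5q-nonisolated")
  if (tok == "del(5q)" || grepl("^del\\(5\\)\\(q", tok)) return("del5q")
  if (tok == "-7" || tok == "del(7q)" || grepl("^del\\(7\\)\\(q", tok))
    return("-7/7q-")
  if (tok == "-20" || tok == "del(20q)" || grepl("^del\\(20\\)\\(q", tok))
    return("-20/20q-")
  if (tok == "-17" || tok == "del(17p)" || grepl("^del\\(17\\)\\(p", tok) ||
      grepl("^i\\(17", tok) ||
      (grepl("^t\\(", tok) && grepl("(\\(|;)17(;|\\))", tok)))
    return("-17/17p-/t17")
  if (tok == "-9" || tok == "del(9q)" || grepl("^del\\(9\\)\\(q", tok))
    return("-9/9q-")
  if (tok == "-13" || tok == "del(13q)" || grepl("^del\\(13\\)\\(q", tok))
    return("-13/13q-")
  if (tok == "-18") return("-18")
  if (tok == "-12" || tok == "del(12p)" || grepl("^del\\(12\\)\\(p", tok))
    return("-12/12p-")
  if (tok == "-16" || tok == "del(16q)" || grepl("^del\\(16\\)\\(q", tok))
    return("-16/16q-")
  NA_character_
}

#' Parse an ISCN-like karyotype string into coded events
#'
#' A light-weight tokenizer for comma-separated ISCN-style karyotypes
#' (e.g. `"47,XY,+8"`). It extracts the recurrent abnormalities of the
#' [cyto_vocabulary()], ignores the modal chromosome count and sex
#' designators, strips clone-size brackets, and records — but does not fail
#' on — tokens it cannot interpret. When three or more distinct clonal
#' abnormalities are present (recognised or not), the `"complex"` code is
#' added. del(5q) as the sole abnormality codes as `"isolated_del5q"`,
#' otherwise as `"-5/5q-nonisolated"`. der(1;7) is coded as its own event and
#' deliberately not counted as `"-7/7q-"`.
#'
#' @param iscn a single karyotype string; `""`, `NA` and normal karyotypes
#'   return an empty set.
#' @return character vector of vocabulary codes (a set, unordered); attribute
#'   `"unrecognized"` lists abnormal tokens that could not be mapped.
#' @examples
#' parse_karyotype("46,XY")                      # character(0)
#' parse_karyotype("47,XY,+8")                   # "+8"
#' parse_karyotype("46,XX,der(1;7)(q10;p10)")    # "der(1;7)"
#' @export
parse_karyotype <- function(iscn) {
  stopifnot(length(iscn) == 1L)
  if (is.na(iscn) || !nzchar(trimws(iscn))) {
    out <- character(0)
    attr(out, "unrecognized") <- character(0)
    return(out)
  }
  s <- gsub("\\[[^]]*\\]", "", iscn)      # clone sizes [12], [cp3]
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  # drop modal count (possibly a range like 45~47) and sex-chromosome field
  toks <- toks[!grepl("^[0-9]+([~-][0-9]+)?(<[0-9]n>)?$", toks)]
  toks <- toks[!grepl("^[XY]+$", toks)]
  toks <- toks[!toks %in% c("idem", "sl", "sdl", "cp")]

  mapped <- vapply(toks, .map_cyto_token, character(1), USE.NAMES = FALSE)
  unrecognized <- unique(toks[is.na(mapped)])
  codes <- unique(mapped[!is.na(mapped)])

  # distinct clonal abnormalities for the complexity count: every mapped
  # event (del5q placeholder included) plus every unmapped abnormal token
  n_abn <- length(codes) + length(unrecognized)
  if ("del5q" %in% codes) {
    codes <- setdiff(codes, "del5q")
    codes <- c(codes, if (n_abn == 1L) "isolated_del5q" else
                                       "-5/5q-nonisolated")
  }
  if (n_abn >= 3L) codes <- union(codes, "complex")
  codes <- sort(unique(codes))
  attr(codes, "unrecognized") <- unrecognized
  codes
}
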