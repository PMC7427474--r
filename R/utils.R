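# Internal helpers shared across modules.

# Chromosome labels: accept "1" or "chr1" on input, emit "chr"-prefixed.
norm_chrom <- function(x) {
  x <- trimws(as.character(x))
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# Numeric rank for chromosome sorting: 1..22, X, Y, MT, then others.
chrom_rank <- function(x) {
  base <- sub("^chr", "", as.character(x))
  n <- suppressWarnings(as.integer(base))
  ifelse(!is.na(n), n,
    ifelse(base == "X", 23L,
      ifelse(base == "Y", 24L,
        ifelse(base %in% c("M", "MT"), 25L, 26L))))
}

split_csv <- function(x) strsplit(as.character(x), ",", fixed = TRUE)

int_csv <- function(x) lapply(split_csv(x), as.integer)

join_csv <- function(x) vapply(x, paste, character(1), collapse = ",")

# Standard microhap nomenclature: mh + 2-character chromosome code +
# >=2-letter lab designator + "-" + identifier, e.g. mh01KK-172.
MH_NAME_PATTERN <- "^mh(0[1-9]|1[0-9]|2[0-2]|0?[XY])[A-Za-z]{2,}-[A-Za-z0-9._]+$"

is_standard_marker_name <- function(name) {
  grepl(MH_NAME_PATTERN, name)
}

# Deterministic per-key substream seed so that simulating additional markers
# never perturbs the draws of existing ones. Plain polynomial string hash,
# folded into [0, 2^31 - 2].
substream_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 131 + cp) %% 2147483629
  }
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
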