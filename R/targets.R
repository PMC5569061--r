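# Canonical seed-site scanning: 6mer, 7mer-A1, 7mer-m8 and 8mer matches of a
# mature miRNA seed in UTR sequences (sense orientation).

rc_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' Scan a UTR for canonical seed sites
#'
#' A locus matches when a UTR window equals the reverse complement of miRNA
#' positions 2-7 (the 6mer core). The window is extended to 7mer-m8 when the
#' preceding UTR base pairs with miRNA position 8, to 7mer-A1 when the base
#' following the core is an adenine (required to be `A` in the UTR regardless
#' of miRNA position 1), and to 8mer when both hold. Each core locus is
#' reported once with its highest-priority type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); overlapping loci are all reported.
#'
#' @param mature mature miRNA sequence (>= 8 nt, RNA or DNA; T is
#'   normalized to U).
#' @param utr UTR sequence in sense orientation.
#' @param mirna_id,utr_id identifiers copied into the output.
#' @return data.frame: `mirna_id`, `utr_id`, `site_type`, `utr_position`
#'   (0-based start of the full site), `site_seq`.
#' @export
scan_utr <- function(mature, utr, mirna_id = NA_character_,
                     utr_id = NA_character_) {
  mature <- chartr("Tt", "Uu", toupper(mature))
  utr <- chartr("Tt", "Uu", toupper(utr))
  if (nchar(mature) < 8) stop("mature must be at least 8 nt")
  n <- nchar(utr)
  empty <- data.frame(mirna_id = character(), utr_id = character(),
                      site_type = character(), utr_position = integer(),
                      site_seq = character(), stringsAsFactors = FALSE)
  if (n < 6) return(empty)
  core <- rc_rna(substr(mature, 2, 7))
  m8c <- rc_rna(substr(mature, 8, 8))
  starts <- which(substring(utr, 1:(n - 5), 6:n) == core)  # 1-based core start
  if (!length(starts)) return(empty)
  rows <- lapply(starts, function(i) {
    has_m8 <- i > 1 && substr(utr, i - 1, i - 1) == m8c
    has_a1 <- i + 6 <= n && substr(utr, i + 6, i + 6) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; from <- i - 1; to <- i + 6
    } else if (has_m8) {
      type <- "7mer-m8"; from <- i - 1; to <- i + 5
    } else if (has_a1) {
      type <- "7mer-A1"; from <- i; to <- i + 6
    } else {
      type <- "6mer"; from <- i; to <- i + 5
    }
    data.frame(mirna_id = mirna_id, utr_id = utr_id, site_type = type,
               utr_position = as.integer(from - 1),
               site_seq = substr(utr, from, to), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan many miRNA/UTR pairs
#' @param matures named character vector of mature sequences.
#' @param utrs named character vector of UTR sequences.
#' @return row-bound site data.frame over all pairs.
#' @export
scan_all_utrs <- function(matures, utrs) {
  out <- list()
  for (m in names(matures)) {
    for (u in names(utrs)) {
      out[[length(out) + 1L]] <- scan_utr(matures[[m]], utrs[[u]], m, u)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- scan_utr("ACGUACGU", "")  # empty frame
  rownames(res) <- NULL
  res
}

#' Summarize seed sites
#'
#' @param sites site data.frame from [scan_utr()]/[scan_all_utrs()].
#' @return list with `per_mirna` (data.frame `mirna_id`, one column per site
#'   type, `total`) and `per_utr` (data.frame `utr_id`, `total`).
#' @export
site_summary <- function(sites) {
  types <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  if (nrow(sites) == 0) {
    return(list(
      per_mirna = data.frame(mirna_id = character(),
                             matrix(integer(), 0, 4,
                                    dimnames = list(NULL, types)),
                             total = integer(), check.names = FALSE),
      per_utr = data.frame(utr_id = character(), total = integer())
    ))
  }
  tab <- table(sites$mirna_id, factor(sites$site_type, levels = types))
  per_mirna <- data.frame(mirna_id = rownames(tab),
                          as.data.frame.matrix(tab),
                          total = as.integer(rowSums(tab)),
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(per_mirna) <- NULL
  ut <- table(sites$utr_id)
  per_utr <- data.frame(utr_id = names(ut), total = as.integer(ut),
                        stringsAsFactors = FALSE)
  list(per_mirna = per_mirna[order(per_mirna$mirna_id, method = "radix"), ,
                             drop = FALSE],
       per_utr = per_utr[order(per_utr$utr_id, method = "radix"), ,
                         drop = FALSE])
}
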