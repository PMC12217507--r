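#' Canonical keys for unordered gene pairs
#'
#' A paralog pair (A, B) is the same object as (B, A): sequence identity,
#' dLFC and hit membership are all properties of the unordered pair. All
#' internal bookkeeping therefore uses a canonical key in which the two
#' symbols are sorted lexicographically (C locale) and joined with "|".
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled).
#' @return `pair_key()` returns a character vector of canonical keys.
#' @examples
#' pair_key("SMARCA4", "SMARCA2") == pair_key("SMARCA2", "SMARCA4")
#' @export
pair_key <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) {
    stop("a pair must consist of two distinct genes: ",
         gene_a[which(gene_a == gene_b)[1L]])
  }
  swap <- cmp_gt(gene_a, gene_b)
  lo <- ifelse(swap, gene_b, gene_a)
  hi <- ifelse(swap, gene_a, gene_b)
  paste(lo, hi, sep = "|")
}

# locale-independent string comparison (C collation), so canonical order
# does not depend on the session locale
cmp_gt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a > b
}

#' @rdname pair_key
#' @param key Character vector of canonical pair keys.
#' @return `pair_genes()` returns a two-column character matrix
#'   (`gene_a`, `gene_b`) recovering the sorted symbols from keys.
#' @export
pair_genes <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed pair key: ", key[which(bad)[1L]])
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("gene_a", "gene_b")))
  m
}
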