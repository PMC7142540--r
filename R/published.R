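#' Published COI identification results for 28 retail cod samples
#'
#' The COI barcoding survey behind the built-in panel: 28 retail "Xue Yu"
#' (cod) products from Chinese supermarkets, each identified by its best
#' GenBank hit and percent similarity. Six samples were \emph{G. morhua},
#' twelve \emph{R. hippoglossoides} and ten \emph{D. eleginoides}; all 28
#' passed the 98\% similarity acceptance rule and went on to RAD
#' sequencing. The table is provided in the \code{\link{countPassing}} /
#' \code{\link{assignSpeciesSet}} hit format.
#'
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{pinyin_group}, \code{label}, \code{status}, \code{accession},
#'   \code{species}, \code{identity} (percent).
#' @examples
#' hits <- codBarcodingResults()
#' countPassing(hits, 98)   # 28
#' @export
codBarcodingResults <- function() {
  df <- read.table(text = "
sample_id|pinyin_group|label|status|accession|species|identity
NO2|Da xi yang xue|Iceland Atlantic cod|In bulk|LS999407.1|G. morhua|99.41
NO3|Da xi yang xue|Iceland Atlantic cod|In bulk|LS999407.1|G. morhua|99.56
NO5|Da xi yang xue|Wild cod|Prepackaged|LS999106.1|G. morhua|99.26
NO8|Da xi yang xue|Wild cod|Prepackaged|LS999106.1|G. morhua|99.56
NO9|Da xi yang xue|Norwegian Atlantic cod|Prepackaged|MK011280.1|G. morhua|99.55
NO10|Da xi yang xue|Norwegian Atlantic cod|Prepackaged|LS999407.1|G. morhua|99.41
NO11|Bian xue|Greenland cod|Prepackaged|AM749133.1|R. hippoglossoides|99.12
NO12|Bian xue|Greenland cod|Prepackaged|AM749133.1|R. hippoglossoides|99.12
NO19|Bian xue|Greenland cod|Prepackaged|MH032539.1|R. hippoglossoides|99.85
NO20|Bian xue|Greenland flat cod|In bulk|AM749132.1|R. hippoglossoides|98.38
NO21|Bian xue|Greenland flat cod|In bulk|MH032539.1|R. hippoglossoides|98.96
NO23|Bian xue|Greenland flat cod|In bulk|AM749130.1|R. hippoglossoides|98.96
NO24|Bian xue|Greenland flat cod|In bulk|HM421730.1|R. hippoglossoides|100
NO26|Bian xue|Greenland halibut|Prepackaged|KC015874.1|R. hippoglossoides|99.85
NO27|Bian xue|Greenland halibut|Prepackaged|KF386352.1|R. hippoglossoides|100
NO28|Bian xue|Greenland halibut|Prepackaged|MH032539.1|R. hippoglossoides|98.96
NO30|Bian xue|Greenland halibut|Prepackaged|KF386350.1|R. hippoglossoides|98.96
NO31|Bian xue|Greenland halibut|Prepackaged|MH032539.1|R. hippoglossoides|98.96
NO32|Yin xue|French cod|In bulk|AB723627.1|D. eleginoides|98.97
NO35|Yin xue|French cod|In bulk|JN640625.1|D. eleginoides|99.54
NO36|Yin xue|French toothfish|In bulk|AB723627.1|D. eleginoides|98.97
NO37|Yin xue|French toothfish|Prepackaged|AB723627.1|D. eleginoides|99.56
NO40|Yin xue|French toothfish|Prepackaged|AB723627.1|D. eleginoides|98.37
NO41|Yin xue|French toothfish|Prepackaged|EU752077.1|D. eleginoides|98.61
NO45|Yin xue|French toothfish|Prepackaged|EF609344.1|D. eleginoides|98.47
NO46|Yin xue|French toothfish|Prepackaged|AB723627.1|D. eleginoides|98.97
NO47|Yin xue|French toothfish|Prepackaged|EU074416.1|D. eleginoides|98.61
NO48|Yin xue|French toothfish|Prepackaged|AB723627.1|D. eleginoides|98.97
", header = TRUE, sep = "|", stringsAsFactors = FALSE, strip.white = TRUE)
  df$identity <- as.numeric(df$identity)
  df
}

#' Sample counts per species in the published survey
#'
#' @return Named integer vector: samples per species among the 28 retail
#'   products (6 \emph{G. morhua}, 12 \emph{R. hippoglossoides}, 10
#'   \emph{D. eleginoides}).
#' @export
codSampleCounts <- function() {
  hits <- codBarcodingResults()
  tab <- table(hits$species)
  setNames(as.integer(tab[c("G. morhua", "R. hippoglossoides",
                            "D. eleginoides")]),
           c("G. morhua", "R. hippoglossoides", "D. eleginoides"))
}
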