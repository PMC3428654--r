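# Packaged count fixtures from the published sesame genic-SSR survey.

#' Load a packaged count fixture
#'
#' The package ships the printed count tables of a published sesame
#' genic-SSR transcriptome survey as plain-text fixtures, used for
#' consistency tests and to shape the simulator's default distributions:
#'
#' * `"table2"` — locus counts by classification and unit-size subtype at
#'   the >=15 bp and >=18 bp thresholds;
#' * `"table4"` — copy-number histogram of perfect loci (>=15 bp) by unit
#'   size;
#' * `"motif_classes"` — counts of the four most abundant canonical motif
#'   classes among perfect loci;
#' * `"totals"` — headline totals (transcripts, total bp, SSR counts,
#'   primer/marker/allele counts).
#'
#' @param name one of `"table2"`, `"table4"`, `"motif_classes"`, `"totals"`.
#' @return a data frame (for `"totals"`, a named numeric vector).
#' @examples
#' sum(load_fixture("table4")[, -1])  # 6485 perfect loci at >=15 bp
#' @export
load_fixture <- function(name) {
  files <- c(table2 = "table2_classification.tsv",
             table4 = "table4_copy_number.tsv",
             motif_classes = "motif_classes.tsv",
             totals = "totals.tsv")
  if (!is.character(name) || length(name) != 1L || !name %in% names(files)) {
    stop("unknown fixture name; available: ",
         paste(names(files), collapse = ", "))
  }
  path <- system.file("extdata", files[[name]], package = "ssrmine",
                      mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (name == "totals") {
    return(stats::setNames(as.numeric(df$value), df$key))
  }
  df
}
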