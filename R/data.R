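#' Reference contact-frequency table for the OsHKT2;2 coordination region
#'
#' The reported per-residue cation contact frequencies (absolute counts
#' and percentages of frames within 4 A, per species and combined) for
#' the extracellular coordination site of OsHKT2;2 and its neighboring
#' residues, aggregated over three 100 ns MD replicates. The total frame
#' count behind the counts was not reported, so `n_frames` is `NA` and
#' combined relatives fall back to printed 2-decimal arithmetic in
#' [combine_species()].
#'
#' @param site_members_only return only the four site-forming residues
#'   (P71, D75, D501, K504)?
#' @return a `contact_table` (see [as_contact_table()]) with an extra
#'   logical `site_member` column.
#' @export
oshkt22_contact_table <- function(site_members_only = FALSE) {
  path <- system.file("extdata", "oshkt22_contact_frequencies.tsv",
                      package = "ionsite", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (site_members_only) tab <- tab[tab$site_member, , drop = FALSE]
  as_contact_table(tab, species = c("Na", "K"), n_frames = NA,
                   replicate_ids = c("md1", "md2", "md3"))
}
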