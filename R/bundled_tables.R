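#' @title Bundled reference tables
#' @description Literature-derived reference data for the abEC1.1-hCx26
#'   system, shipped as plain tab-separated fixtures: the connexin-family
#'   epitope motifs (EC1 54-58 / EC2 175-176), the channel-side and
#'   antibody-side interaction-probability tables from the source
#'   molecular-dynamics analysis, and the measured residual hemichannel
#'   conductances per isoform. Files are integrity-checked against a bundled
#'   md5 manifest on every load.
#' @name bundled_tables
NULL

bundled_path <- function(name) {
  p <- system.file("extdata", name, package = "connexitope")
  if (!nzchar(p)) stop("bundled fixture not found: ", name)
  p
}

read_bundled <- function(name) {
  p <- bundled_path(name)
  man <- utils::read.table(bundled_path("checksums.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  want <- man$md5[man$file == name]
  if (length(want) == 1L) {
    got <- unname(tools::md5sum(p))
    if (!identical(got, want)) {
      warning("bundled fixture ", name, " fails its checksum; it may have been edited")
    }
  }
  utils::read.table(p, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Connexin-family epitope motif table
#'
#' One row per human connexin isoform: gene symbol (transcribed as printed in
#' the source, including its typographic oddities), protein name, the EC1
#' 54-58 and EC2 175-176 motifs, and free-text annotations.
#' @return data.frame with 20 rows.
#' @export
cx_motif_table <- function() read_bundled("abec11_epitope_motifs.tsv")

#' Channel-side interaction probabilities (reference)
#'
#' Interaction probability of hCx26 hemichannel residues with the antibody,
#' percent of analyzed simulation time, by protomer and loop region.
#' @return data.frame with columns `protomer`, `region`, `residue`, `resno`,
#'   `probability_pct`.
#' @export
cx_channel_contact_table <- function() read_bundled("abec11_channel_contacts.tsv")

#' Antibody-side interaction probabilities (reference)
#'
#' Interaction probability of antibody residues with the hemichannel's
#' extracellular domain, percent, by chain (HC/LC) and region (CDR1-3,
#' constant).
#' @return data.frame with columns `chain`, `region`, `residue`, `resno`,
#'   `probability_pct`.
#' @export
cx_antibody_contact_table <- function() read_bundled("abec11_antibody_contacts.tsv")

#' Residual hemichannel conductance per isoform (reference)
#'
#' Measured membrane conductance after antibody application as a percentage
#' of the pre-application control, per connexin isoform. Values split
#' bimodally: 16-25% (inhibited: hCx26, hCx30, hCx32) vs 73-98% (all others).
#' The antibody was applied at 952 nM in the source experiments (recorded
#' here as provenance; it plays no computational role).
#' @return data.frame with columns `isoform`, `residual_pct`, `source`.
#' @export
cx_conductance_table <- function() read_bundled("abec11_residual_conductance.tsv")

#' Alias map joining conductance isoform names to motif-table names
#'
#' The conductance data name one isoform "hCx30.2/31.3" while the motif table
#' prints "hCx30.2"; this map makes the join explicit.
#' @return named character vector.
#' @export
cx_isoform_aliases <- function() c("hCx30.2/31.3" = "hCx30.2")

# fixed pseudo-random scaffold the synthetic family sequences are built on;
# positions 54-58 and 175-176 are the motif slots (hCx26 numbering)
.scaffold_200 <- paste0(
  "AGPRNESFNCWRQTNLVCFNFSDNDDLEIVCPKNFKPVKSHVFFMETIKDRY",
  "KGERANGPEIGSGTWATYGFTDYRTIEPANDWPAGVYVAYLCEFRATKPNWV",
  "NKDCTCLPLQGWNNCECGRTNEEDMSGGAEWPDFGWRLGMWEVSVEWGNAFG",
  "EQPCVSQVRITMLSHPPINRRLILISAYFLMAVDDCPNHPRAQE")

splice_motifs <- function(scaffold, ec1, ec2) {
  ch <- strsplit(scaffold, "")[[1]]
  ch[54:58] <- strsplit(ec1, "")[[1]]
  ch[175:176] <- strsplit(ec2, "")[[1]]
  paste(ch, collapse = "")
}

#' Synthetic reference (hCx26) scaffold sequence
#'
#' A 200-residue synthetic scaffold carrying the hCx26 motifs NTLQP at 54-58
#' and PN at 175-176. It is *not* the real hCx26 sequence — true full-length
#' connexin sequences are not bundled; only motif positions are meaningful.
#' @return character scalar.
#' @export
reference_scaffold_sequence <- function() splice_motifs(.scaffold_200, "NTLQP", "PN")

# indel edits applied to a few isoforms so alignment-based position mapping
# is exercised on shifted coordinates (all edits far from the motif slots)
.family_edits <- list(
  hCx43 = function(s) paste0("MGD", s),                      # +3 N-terminal extension
  hCx45 = function(s) paste0(substr(s, 1, 109), substr(s, 112, nchar(s))),  # 2-res deletion at 110-111
  hCx37 = function(s) paste0(substr(s, 1, 120), "GS", substr(s, 121, nchar(s))))  # 2-res insertion after 120

#' Write the synthetic connexin-family FASTA
#'
#' One synthetic sequence per motif-table isoform: the common scaffold with
#' that isoform's EC1/EC2 motifs spliced in at the hCx26-numbered positions.
#' Three isoforms additionally carry small indels away from the motifs
#' (N-terminal extension, internal deletion, internal insertion) so that
#' alignment-based position mapping is exercised. Headers are
#' `gene|protein synthetic scaffold`.
#'
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(path) {
  tab <- cx_motif_table()
  seqs <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- splice_motifs(.scaffold_200, tab$ec1_54_58[i], tab$ec2_175_176[i])
    ed <- .family_edits[[tab$protein[i]]]
    if (!is.null(ed)) s <- ed(s)
    seqs[i] <- s
  }
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- paste0(tab$gene, "|", tab$protein, " synthetic scaffold")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
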