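# Synthetic fixture libraries: protein-domain motif exemplars per LTR
# retroelement lineage and tRNA 3'-terminal 18-mers. These are synthetic
# stand-ins authored for this package (no external database is bundled);
# they only need to be mutually distinct and stable.

.DOMAIN_MOTIFS <- local({
  m <- matrix(c(
    "Tekay", "GAG", "GDYESQSLHEDDAYHAPMRFSMHD",
    "Tekay", "PROT", "YAEDIMYGMGDIFHPSHNLWCELQ",
    "Tekay", "RT", "VKGPSGYLWPASKIYNMMVKEENS",
    "Tekay", "RH", "WMYVNMAFFLEKQLVNVNMQDIEG",
    "Tekay", "INT", "QEFMDCHQFISNEEQVEFWSKSKL",
    "Retand", "GAG", "DMVAWCIQGYSFGSNKGKYTNHWI",
    "Retand", "PROT", "IYRLQWLRDAGPWAAGLQFESSFT",
    "Retand", "RT", "KQARIHCGFDKYCNNLTHREVCNT",
    "Retand", "RH", "GDNSICVLNGYDNTLDREKPFYNI",
    "Retand", "INT", "GPEKCERWEDCKPHSKGWPHWPTI",
    "CRM", "GAG", "MVCQQYPMLIQGSNTDWPIFTWSQ",
    "CRM", "PROT", "PMGDQMKIPVRMDEYTEIHAKPRM",
    "CRM", "RT", "IYICHQTTKWGLQIQAIPRNFGQN",
    "CRM", "RH", "FENTTENALRNRMKEMAQKVDARG",
    "CRM", "INT", "RTFVAGIPLWPTIECPKCPDCHMV",
    "Angela", "GAG", "NEQWCPGSAGAVIIPNNNLVNVRE",
    "Angela", "PROT", "RHPGLHSGCYVGPHGQGCMAHSIY",
    "Angela", "RT", "INGEKVRGRPRCKEADRDVMTYVF",
    "Angela", "RH", "DPSFPWINWFNIATSLRAWPADCN",
    "Angela", "INT", "MNADDKERVQENMAELMRPFSSPA",
    "SIRE", "GAG", "VAVGSSWAAMEAIKHAGALAFNDH",
    "SIRE", "PROT", "TASLFERGAVDREYPPTRISIRMN",
    "SIRE", "RT", "MCPFVSYGTHFQTRRHDEMHWWLH",
    "SIRE", "RH", "DVFMFPRKQYCRMYVTSPQASFAF",
    "SIRE", "INT", "YSCFIWKYWYADAGWIRDRMAFEK",
    "Ale", "GAG", "MQTMCSSFEKAPLSIEPYLDDKHM",
    "Ale", "PROT", "MATIASNSLIWVDGNKGIGYCDYE",
    "Ale", "RT", "RTYDCLVTNMMTASYPASCGKRND",
    "Ale", "RH", "GALQWGDGHRRNWWVERLPWGLCH",
    "Ale", "INT", "FEKFFMTCAYWQVLDIHWCCSNES"
  ), ncol = 3, byrow = TRUE)
  sup <- ifelse(m[, 1] %in% c("Tekay", "Retand", "CRM"),
                "Ty3/gypsy", "Ty1/copia")
  data.frame(lineage = m[, 1], superfamily = sup, domain = m[, 2],
             peptide = m[, 3], stringsAsFactors = FALSE)
})

.TRNA_18MERS <- c(
  "tRNA-Met" = "ACGGAGCCGCACTATCGT",
  "tRNA-Lys" = "CTTAGGAAAGGGTCTGCC",
  "tRNA-Trp" = "AAGGCCCGATAGAGTGAC",
  "tRNA-Gly" = "CCAAACTCTTTCAAATGC",
  "tRNA-Ile" = "GGGTTCCGCCATGGACTC")

# domain order per superfamily (genomic order of the polyprotein domains)
.DOMAIN_ORDER <- list(
  "Ty1/copia" = c("GAG", "PROT", "INT", "RT", "RH"),
  "Ty3/gypsy" = c("GAG", "PROT", "RT", "RH", "INT"))

#' Synthetic protein-domain motif library
#'
#' One short peptide exemplar per (lineage, domain) pair for the bundled
#' synthetic lineages, used to call protein domains and lineage in LTR
#' element interiors. The peptides are synthetic fixtures, not database
#' sequences.
#'
#' @return data.frame with columns \code{lineage}, \code{superfamily},
#'   \code{domain}, \code{peptide}.
#' @export
domainMotifLibrary <- function() .DOMAIN_MOTIFS

#' Synthetic tRNA 3'-terminal 18-mer library
#'
#' Used both by the generator (to plant primer binding sites complementary
#' to a tRNA 3' end) and by the PBS detector. Synthetic fixtures.
#'
#' @return Named character vector of 18-mers.
#' @export
trnaLibrary <- function() .TRNA_18MERS

#' Expected genomic domain order for a superfamily
#'
#' @param superfamily \code{"Ty1/copia"} or \code{"Ty3/gypsy"}.
#' @return Character vector of domain names in genomic order.
#' @export
domainOrder <- function(superfamily) {
  out <- .DOMAIN_ORDER[[superfamily]]
  if (is.null(out)) stop("unknown superfamily: ", superfamily)
  out
}
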