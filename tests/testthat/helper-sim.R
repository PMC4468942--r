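# strip genome_record attributes down to the gene table for comparisons
as_genes_df <- function(g) {
  df <- as.data.frame(g)
  attr(df, "genome_id") <- NULL
  attr(df, "group") <- NULL
  attr(df, "size_kb") <- NULL
  attr(df, "sequence") <- NULL
  df
}
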