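# Hand-written KGML fixtures and small data builders used across tests.

kgml_basic <- function() {
  paste0(
    '<pathway name="path:ko00900" number="00900" title="basic">\n',
    '  <entry id="e1" name="ko:K00001" type="ortholog"/>\n',
    '  <entry id="e2" name="ko:K00002" type="ortholog"/>\n',
    '  <entry id="c1" name="cpd:C00022" type="compound"/>\n',
    '  <relation entry1="e1" entry2="e2" type="ECrel">\n',
    '    <subtype name="compound" value="c1"/>\n',
    '  </relation>\n',
    '</pathway>')
}

kgml_empty <- function() {
  paste0('<pathway name="path:ko00910" number="00910" title="empty">\n',
         '  <entry id="e1" name="ko:K00009" type="ortholog"/>\n',
         '</pathway>')
}

kgml_multi_ko <- function() {
  paste0(
    '<pathway name="path:ko00920" number="00920" title="grouped">\n',
    '  <entry id="e1" name="ko:K00001 ko:K00002" type="ortholog"/>\n',
    '  <entry id="e2" name="ko:K00003" type="ortholog"/>\n',
    '  <entry id="c1" name="cpd:C00031" type="compound"/>\n',
    '  <relation entry1="e1" entry2="e2" type="ECrel">\n',
    '    <subtype name="compound" value="c1"/>\n',
    '  </relation>\n',
    '</pathway>')
}

# same K00001-K00002 edge as kgml_basic but via a different compound
kgml_basic_alt <- function() {
  gsub('C00022', 'C00033',
       gsub('00900', '00901', kgml_basic(), fixed = TRUE), fixed = TRUE)
}

# one metabolic map (producer chain) plus one transporter map sharing the
# producer; the producer-transporter edge carries the uptake compound
kgml_boundary_pair <- function() {
  met <- paste0(
    '<pathway name="path:ko00010" number="00010" title="met">\n',
    '  <entry id="1" name="ko:K00010" type="ortholog"/>\n',
    '  <entry id="2" name="ko:K00011" type="ortholog"/>\n',
    '  <entry id="3" name="cpd:C00022" type="compound"/>\n',
    '  <relation entry1="1" entry2="2" type="ECrel">\n',
    '    <subtype name="compound" value="3"/>\n',
    '  </relation>\n',
    '</pathway>')
  tra <- paste0(
    '<pathway name="path:ko02010" number="02010" title="abc">\n',
    '  <entry id="1" name="ko:K00010" type="ortholog"/>\n',
    '  <entry id="2" name="ko:K00099" type="ortholog"/>\n',
    '  <entry id="3" name="cpd:C00022" type="compound"/>\n',
    '  <relation entry1="1" entry2="2" type="ECrel">\n',
    '    <subtype name="compound" value="3"/>\n',
    '  </relation>\n',
    '</pathway>')
  list(met = met, tra = tra)
}

# a scored_pairs data frame built directly (bypassing profiles)
make_scored <- function(ko_a, ko_b, score, pair_class = "unclassified",
                        compounds = NULL, defined = TRUE) {
  n <- length(ko_a)
  df <- data.frame(ko_a = ko_a, ko_b = ko_b,
                   dissimilarity = NA_real_, cooccurrence = NA_real_,
                   score = score, stringsAsFactors = FALSE)
  df$compounds <- if (is.null(compounds)) rep(list(character(0)), n)
                  else compounds
  df$pair_class <- rep_len(pair_class, n)
  df$defined <- rep_len(defined, n)
  class(df) <- c("scored_pairs", "data.frame")
  df
}

tiny_spec <- function(...) {
  community_spec(n_genera = 8, n_kos = 24, n_samples = 12,
                 n_planted_pairs = 2, n_boundary_pairs = 2, ...)
}
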