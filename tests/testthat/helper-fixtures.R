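# Small in-code fixtures shared across test files.

synd_tree <- syndermatan_tree()

five_tip_newick <- "(Out,(Mono,(Bdel,(Seis,Acan)Pararotatoria)Hemirotifera)Syndermata)Root;"

# tiny hand-built matrix: 3 taxa x 5 characters
tiny_matrix <- function() {
  character_matrix(matrix(
    c(1L, 1L, 0L, 0L, 1L,
      1L, 0L, 0L, 0L, 1L,
      0L, 1L, 0L, 1L, 1L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), paste0("c", 1:5))))
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
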