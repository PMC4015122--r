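{
  "snapshot_id": "synthetic-2013",
  "comment": "Hand-curated synthetic snapshot of a category->package classification, shipped so recommendations work offline and reproducibly. Not a dump of any live repository.",
  "category_to_packages": {
    "Metabolomics": ["CAMERA", "MAIT", "metaMS", "xcms"],
    "MassSpectrometry": ["MSnbase", "mzR", "xcms"],
    "Proteomics": ["MSnbase", "RforProteomics", "isobar"],
    "Microarray": ["affy", "limma", "oligo", "vsn"],
    "DifferentialExpression": ["DESeq", "edgeR", "limma"],
    "ExonArray": ["exonmap", "oligo"],
    "Transcription": ["affy", "limma"],
    "GeneExpression": ["Biobase", "limma"],
    "Sequencing": ["Rsamtools", "ShortRead"],
    "RNAseq": ["DESeq", "edgeR"],
    "ChIPseq": ["ChIPpeakAnno", "chipseq"],
    "ChIPchip": ["Ringo"],
    "CpGIsland": [],
    "Methylseq": ["methylKit"],
    "DNAMethylation": ["methylumi", "minfi"],
    "SNP": ["snpStats"],
    "GeneticVariability": ["snpStats"],
    "CopyNumberVariants": ["CGHbase", "DNAcopy"],
    "aCGH": ["aCGH", "DNAcopy"],
    "Regulation": [],
    "FlowCytometry": ["flowCore"],
    "qPCR": ["HTqPCR"]
  }
}
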