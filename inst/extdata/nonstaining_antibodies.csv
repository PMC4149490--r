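antigen,expected_cell_type,cell_type_analyzed
CD103,intestinal intraepithelial lymphocytes (IEL),FALSE
CD41b,platelets,FALSE
PAC-1,platelets,FALSE
CD1a,"cortical thymocytes, dendritic cells and Langerhans cells; DOES NOT react with PBMCs",FALSE
CD209,"dendritic cells, vascular endothelial cells",FALSE
CD150,"T cells, B cells, thymocytes, germinal center and dendritic cells",TRUE
CD16b,neutrophils,TRUE
FMC7,B lymphocytes,TRUE
CD197,lymphocytes,TRUE
CD129,"low levels on eosinophils, mast cells, macrophages, B lymphocytes, T lymphocytes, and erythroid progenitors",TRUE
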