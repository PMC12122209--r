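sample_id,image_path,category
patch001,,leukoplakia_with_dysplasia
patch002,,leukoplakia_with_dysplasia
patch003,,leukoplakia_without_dysplasia
patch004,,leukoplakia_without_dysplasia
patch005,,OSCC
patch006,,oscc
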