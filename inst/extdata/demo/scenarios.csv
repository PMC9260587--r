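# ethoclust config_hash=04cba3d0 seed=424242
scenario,pc_num,silhouette,cluster_num,filtered_cluster_num,num_samples,retained_sizes
1,1,0.950869,2,2,21,"14(c-0), 7(c-1)"
2,2,0.738313,2,2,21,"14(c-0), 7(c-1)"
3,3,0.665027,2,2,21,"14(c-0), 7(c-1)"
4,4,0.609263,2,2,21,"14(c-0), 7(c-1)"
5,5,0.595608,2,2,21,"14(c-0), 7(c-1)"
6,6,0.593111,2,2,21,"14(c-0), 7(c-1)"
7,7,0.58545,2,2,21,"14(c-0), 7(c-1)"
8,8,0.583398,2,2,21,"14(c-0), 7(c-1)"
9,9,0.582777,2,2,21,"14(c-0), 7(c-1)"
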